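# Geometric embedding for gen_box(): breadth-first placement of bonded
# molecule clusters with exact hydrogen-bond geometry and clearance rules
# that make accidental bonds impossible (non-planted oxygen-oxygen pairs are
# kept beyond the 3.5 A detection cutoff, so no unplanned donor-acceptor
# pair can ever satisfy the distance criterion).

# local template of a small molecule: three hydroxyl-like sites at the
# vertices of an equilateral triangle (side 5 A), H pointing radially out
small_local_template <- function() {
  r <- 5.0 / sqrt(3)
  ang <- c(90, 210, 330) * pi / 180
  O <- cbind(r * cos(ang), r * sin(ang), 0)
  u <- O / r
  list(O = O, H = O + .OH_BOND * u)
}

rand_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# rotation matrix taking unit vector a onto unit vector b (Rodrigues)
rot_align <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cc <- sum(a * b)
  if (cc < -1 + 1e-10) {
    p <- perp_basis(a)$u1
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cc)
}

# rotation about unit axis by angle (radians)
rot_axis <- function(axis, angle) {
  vx <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                 axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * vx + (1 - cos(angle)) * vx %*% vx
}

rand_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# random direction within `max_deg` of unit vector u (uniform in solid angle)
cone_dir <- function(u, max_deg = 24) {
  ct <- runif(1, cos(max_deg * pi / 180), 1)
  st <- sqrt(1 - ct^2)
  phi <- runif(1, 0, 2 * pi)
  pb <- perp_basis(u)
  ct * u + st * (cos(phi) * pb$u1 + sin(phi) * pb$u2)
}

# sample an acceptor offset from a donor O with H direction u: anywhere in
# the 24-degree cone at 2.65-3.35 A keeps the planted bond comfortably
# inside the 3.5 A / 30 degree detection criteria while giving the placement
# search geometric freedom
sample_bond_offset <- function(u) {
  runif(1, 2.65, 3.35) * cone_dir(u)
}

# orthonormal pair perpendicular to unit vector a
perp_basis <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- ref - sum(ref * a) * a
  u1 <- u1 / sqrt(sum(u1^2))
  list(u1 = u1, u2 = c(
    a[2] * u1[3] - a[3] * u1[2],
    a[3] * u1[1] - a[1] * u1[3],
    a[1] * u1[2] - a[2] * u1[1]
  ))
}

min_image_one <- function(p, q, box) {
  d <- q - p
  d - box * round(d / box)
}

# Candidate acceptance: minimum separation, O-O clearance, and reverse-angle
# safety at planted acceptors. `exempt` is a 2-column matrix of (i_local, j)
# pairs allowed to be close; j > 0 refers to placed atoms, j < 0 to -local.
candidate_ok <- function(E, cand, exempt, planted, box, min_sep) {
  cxyz <- as.matrix(cand[, c("x", "y", "z")])
  c_o <- role_has(cand$role, "acceptor") | role_has(cand$role, "donor-heavy")
  n_placed <- nrow(E$xyz)
  if (n_placed > 0) {
    d <- min_image_cross_dist(cxyz, E$xyz, box)
    allowed <- matrix(min_sep, nrow(cand), n_placed)
    if (any(c_o) && any(E$is_o)) {
      allowed[c_o, E$is_o] <- .OO_CLEAR
    }
    g <- exempt[exempt[, 2] > 0, , drop = FALSE]
    if (nrow(g)) allowed[g] <- 0.5
    if (any(d < allowed)) return(FALSE)
  }
  if (length(unique(cand$mol)) > 1L) {
    d <- min_image_cross_dist(cxyz, cxyz, box)
    allowed <- matrix(min_sep, nrow(cand), nrow(cand))
    allowed[c_o, c_o] <- .OO_CLEAR
    allowed[outer(cand$mol, cand$mol, "==")] <- 0
    l <- exempt[exempt[, 2] < 0, , drop = FALSE]
    if (nrow(l)) {
      l[, 2] <- -l[, 2]
      allowed[l] <- 0.5
      allowed[l[, c(2, 1), drop = FALSE]] <- 0.5
    }
    if (any(d < allowed)) return(FALSE)
  }
  # no reverse bond at any planted acceptor that carries its own hydrogen:
  # keep the acceptor's H at least 32 degrees away from the donor direction
  for (pp in planted) {
    if (is.null(pp$aH)) next
    v_h <- min_image_one(pp$aO, pp$aH, box)
    v_d <- min_image_one(pp$aO, pp$dO, box)
    cosang <- sum(v_h * v_d) / sqrt(sum(v_h^2) * sum(v_d^2))
    if (acos(pmin(pmax(cosang, -1), 1)) * 180 / pi < 32) return(FALSE)
  }
  TRUE
}

append_candidate <- function(E, cand) {
  offset <- nrow(E$xyz)
  E$xyz <- rbind(E$xyz, as.matrix(cand[, c("x", "y", "z")]))
  E$element <- c(E$element, cand$element)
  E$role <- c(E$role, cand$role)
  E$parent <- c(E$parent,
                ifelse(is.na(cand$parent_local), NA_integer_,
                       cand$parent_local + offset))
  E$mol <- c(E$mol, cand$mol)
  E$class <- c(E$class, cand$class)
  E$is_o <- c(E$is_o,
              role_has(cand$role, "acceptor") | role_has(cand$role, "donor-heavy"))
  offset
}

small_candidate <- function(center, R, mol_id, tmpl, box) {
  O <- sweep(tmpl$O %*% t(R), 2, center, "+")
  H <- sweep(tmpl$H %*% t(R), 2, center, "+")
  list(
    cand = tibble(
      x = c(O[, 1], H[, 1]) %% box[1],
      y = c(O[, 2], H[, 2]) %% box[2],
      z = c(O[, 3], H[, 3]) %% box[3],
      element = c(rep("O", 3), rep("H", 3)),
      role = c(rep("donor-heavy+acceptor", 3), rep("donor-H", 3)),
      parent_local = c(rep(NA_integer_, 3), 1L, 2L, 3L),
      mol = mol_id, class = "small"
    ),
    O = O, H = H
  )
}

# main constructor; raises an `asdkit_retry` condition on geometric dead ends
plant_box <- function(spec, plan) {
  box <- spec$box_edge
  min_sep <- spec$min_separation
  n_ch <- spec$n_chains
  n_sm <- spec$n_small_molecules
  n_w <- spec$n_waters
  id_small <- n_ch + seq_len(n_sm)
  id_water <- n_ch + n_sm + seq_len(n_w)
  ss <- plan[["small-small"]] %||% integer(0)
  sc <- plan[["small-chain"]] %||% integer(0)
  wc <- plan[["water-chain"]] %||% integer(0)
  ws <- plan[["water-small"]] %||% integer(0)
  tmpl <- small_local_template()

  E <- new.env(parent = emptyenv())
  E$xyz <- matrix(numeric(0), 0, 3)
  E$element <- character(0); E$role <- character(0)
  E$parent <- integer(0); E$mol <- integer(0); E$class <- character(0)
  E$is_o <- logical(0)

  chain_used <- rep(0L, n_ch)
  next_chain <- function() {
    if (!n_ch) stop_invalid("plan requires chain bonds but the box has no chains")
    i <- which.min(chain_used)
    if (chain_used[i] >= spec$monomers_per_chain) {
      stop_invalid("infeasible plan: chain acceptor sites exhausted")
    }
    chain_used[i] <<- chain_used[i] + 1L
    i
  }
  chain_snapshot <- chain_used

  small_O <- vector("list", n_sm)
  small_H <- vector("list", n_sm)
  small_atom0 <- rep(NA_integer_, n_sm)

  planted_log <- list()
  log_bond <- function(class, donor_mol, acceptor_mol) {
    planted_log[[length(planted_log) + 1L]] <<-
      tibble(class = class, donor_molecule = donor_mol,
             acceptor_molecule = acceptor_mol)
  }

  try_place_small <- function(s, center, R, acceptor_target = NULL,
                              parent_pos = NULL) {
    sm <- small_candidate(center, R, id_small[s], tmpl, box)
    cand <- sm$cand
    exempt <- matrix(integer(0), 0, 2)
    planted <- list()
    if (!is.null(acceptor_target)) {
      exempt <- rbind(exempt,
                      c(1L, parent_pos$O_idx), c(1L, parent_pos$H_idx),
                      c(4L, parent_pos$O_idx), c(4L, parent_pos$H_idx))
      planted <- c(planted, list(list(
        dO = parent_pos$O, dH = parent_pos$H,
        aO = sm$O[1, ], aH = sm$H[1, ]
      )))
    }
    if (sc[s] > 0) {
      for (j in seq_len(sc[s])) {
        k <- ss[s] + j
        u <- (sm$H[k, ] - sm$O[k, ]) / .OH_BOND
        pos <- (sm$O[k, ] + sample_bond_offset(u)) %% box
        ch <- next_chain()
        cand <- dplyr::bind_rows(cand, tibble(
          x = pos[1], y = pos[2], z = pos[3], element = "O", role = "acceptor",
          parent_local = NA_integer_, mol = ch, class = "chain"
        ))
        idx <- nrow(cand)
        exempt <- rbind(exempt, c(k, -idx), c(k + 3L, -idx))
        planted <- c(planted, list(list(
          dO = sm$O[k, ], dH = sm$H[k, ], aO = pos, aH = NULL
        )))
      }
    }
    if (!candidate_ok(E, cand, exempt, planted, box, min_sep)) {
      chain_used <<- chain_snapshot
      return(FALSE)
    }
    off <- append_candidate(E, cand)
    small_O[[s]] <<- sm$O
    small_H[[s]] <<- sm$H
    small_atom0[s] <<- off
    if (sc[s] > 0) {
      for (j in seq_len(sc[s])) {
        log_bond("small-chain", id_small[s], cand$mol[6L + j])
      }
    }
    TRUE
  }

  # ---- small molecules: forest components --------------------------------
  edges <- if (any(ss > 0)) forest_edges(ss) else matrix(integer(0), ncol = 2)
  adj <- vector("list", n_sm)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  visited <- rep(FALSE, n_sm)
  parent_of <- rep(NA_integer_, n_sm)
  ss_donor_used <- rep(0L, n_sm)

  place_one_small <- function(v, parent_of) {
    par <- parent_of[v]
    for (try in 1:60) {
      chain_snapshot <<- chain_used
      if (is.na(par)) {
        ok <- try_place_small(v, runif(3) * box, rand_rotation())
      } else {
        # the parent donates from its next reserved small-small site;
        # roots donate from site 1, non-roots from site 2 up (site 1 is
        # their acceptor site towards their own parent)
        k_d <- ss_donor_used[par] + (if (is.na(parent_of[par])) 1L else 2L)
        u <- (small_H[[par]][k_d, ] - small_O[[par]][k_d, ]) / .OH_BOND
        offset <- sample_bond_offset(u)
        target <- small_O[[par]][k_d, ] + offset
        w <- offset / sqrt(sum(offset^2))
        R <- if (try %% 4 == 0) {
          rand_rotation()
        } else {
          # grow outward with the growth axis tilted ~55 degrees off the
          # bond: the child extends away from the parent while its own
          # site-1 hydrogen (antiparallel to the growth axis in the
          # template) stays clear of the 32-degree reverse-bond cone
          a_loc <- -tmpl$O[1, ] / sqrt(sum(tmpl$O[1, ]^2))
          tilt_axis <- perp_basis(w)
          phi0 <- runif(1, 0, 2 * pi)
          b <- drop(rot_axis(cos(phi0) * tilt_axis$u1 + sin(phi0) * tilt_axis$u2,
                             55 * pi / 180) %*% w)
          rot_axis(b, runif(1, 0, 2 * pi)) %*% rot_align(a_loc, b)
        }
        center <- target - drop(tmpl$O[1, ] %*% t(R))
        ok <- try_place_small(v, center, R, acceptor_target = target,
                              parent_pos = list(
                                O = small_O[[par]][k_d, ],
                                H = small_H[[par]][k_d, ],
                                O_idx = small_atom0[par] + k_d,
                                H_idx = small_atom0[par] + 3L + k_d
                              ))
      }
      if (ok) {
        if (!is.na(par)) {
          ss_donor_used[par] <<- ss_donor_used[par] + 1L
          log_bond("small-small", id_small[par], id_small[v])
        }
        return(TRUE)
      }
    }
    FALSE
  }

  snapshot_state <- function() {
    list(xyz = E$xyz, element = E$element, role = E$role, parent = E$parent,
         mol = E$mol, class = E$class, is_o = E$is_o,
         chain_used = chain_used, planted_log = planted_log,
         small_O = small_O, small_H = small_H, small_atom0 = small_atom0,
         ss_donor_used = ss_donor_used)
  }
  restore_state <- function(st) {
    E$xyz <- st$xyz; E$element <- st$element; E$role <- st$role
    E$parent <- st$parent; E$mol <- st$mol; E$class <- st$class
    E$is_o <- st$is_o
    chain_used <<- st$chain_used
    planted_log <<- st$planted_log
    small_O <<- st$small_O; small_H <<- st$small_H
    small_atom0 <<- st$small_atom0
    ss_donor_used <<- st$ss_donor_used
  }

  for (s0 in seq_len(n_sm)) {
    if (visited[s0]) next
    queue <- s0
    visited[s0] <- TRUE
    order_bfs <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_bfs <- c(order_bfs, v)
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          parent_of[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    comp_state <- snapshot_state()
    comp_done <- FALSE
    for (comp_try in 1:10) {
      comp_failed <- FALSE
      for (v in order_bfs) {
        if (!place_one_small(v, parent_of)) { comp_failed <- TRUE; break }
      }
      if (!comp_failed) { comp_done <- TRUE; break }
      restore_state(comp_state)
    }
    if (!comp_done) retry_placement("could not place a small-molecule cluster")
  }

  # ---- waters -------------------------------------------------------------
  reserved <- ss + sc  # low site indices of each small already in use
  ws_partner <- allocate_water_partners(ws, reserved, n_sm)
  site_taken <- lapply(seq_len(max(n_sm, 1L)), function(i) integer(0))
  for (w in order(ws, decreasing = TRUE)) {
    placedw <- FALSE
    # reserve this water's acceptor sites on its partner small once
    if (!is.na(ws_partner[w]) && ws[w] > 0L) {
      s <- ws_partner[w]
      avail <- setdiff(seq_len(3L), c(seq_len(reserved[s]), site_taken[[s]]))
      sites_w <- avail[seq_len(ws[w])]
      site_taken[[s]] <- c(site_taken[[s]], sites_w)
    } else {
      sites_w <- integer(0)
    }
    for (try in 1:120) {
      chain_snapshot <- chain_used
      res <- build_water_candidate(
        w, ws, wc, ws_partner, sites_w, small_O, small_H, small_atom0,
        id_small, id_water, box, next_chain
      )
      if (!candidate_ok(E, res$cand, res$exempt, res$planted, box, min_sep)) {
        chain_used <- chain_snapshot
        next
      }
      append_candidate(E, res$cand)
      for (b in res$bonds) log_bond(b$class, b$donor, b$acceptor)
      placedw <- TRUE
      break
    }
    if (!placedw) retry_placement("could not place a water molecule")
  }

  # ---- chain filler sites -------------------------------------------------
  for (ch in seq_len(n_ch)) {
    n_fill <- spec$monomers_per_chain - sum(E$mol == ch)
    for (j in seq_len(max(n_fill, 0L))) {
      okf <- FALSE
      for (try in 1:200) {
        pos <- runif(3) * box
        cand <- tibble(x = pos[1], y = pos[2], z = pos[3], element = "O",
                       role = "acceptor", parent_local = NA_integer_,
                       mol = ch, class = "chain")
        if (candidate_ok(E, cand, matrix(integer(0), 0, 2), list(), box, min_sep)) {
          append_candidate(E, cand)
          okf <- TRUE
          break
        }
      }
      if (!okf) retry_placement("could not place a chain site")
    }
  }

  atoms <- tibble(
    element = E$element,
    x = E$xyz[, 1], y = E$xyz[, 2], z = E$xyz[, 3],
    molecule_id = E$mol, molecule_class = E$class,
    site_role = E$role, parent = E$parent
  )
  cfg <- as_config(atoms, box)
  attr(cfg, "planted") <- if (length(planted_log)) dplyr::bind_rows(planted_log) else
    tibble(class = character(), donor_molecule = integer(),
           acceptor_molecule = integer())
  attr(cfg, "realized_counts") <- realized_from_log(attr(cfg, "planted"),
                                                    id_small, id_water)
  cfg
}

# choose which small each bonded water attaches to (one small per water;
# a two-bond water bridges two free sites of the same small so both bond
# geometries can be satisfied simultaneously)
allocate_water_partners <- function(ws, reserved, n_sm) {
  free <- if (n_sm) 3L - reserved else integer(0)
  partner <- rep(NA_integer_, length(ws))
  for (w in order(ws, decreasing = TRUE)) {
    need <- ws[w]
    if (need == 0L) next
    cand <- which(free >= need)
    if (!length(cand)) {
      stop_invalid("infeasible plan: no small molecule has enough free sites for a water")
    }
    s <- cand[which.max(free[cand])]
    partner[w] <- s
    free[s] <- free[s] - need
  }
  partner
}

build_water_candidate <- function(w, ws, wc, ws_partner, sites_w,
                                  small_O, small_H, small_atom0,
                                  id_small, id_water, box, next_chain) {
  mol <- id_water[w]
  exempt <- matrix(integer(0), 0, 2)
  planted <- list()
  bonds <- list()
  hoh <- 104.5 * pi / 180

  water_atoms <- function(Ow, H1, H2) {
    tibble(
      x = c(Ow[1], H1[1], H2[1]) %% box[1],
      y = c(Ow[2], H1[2], H2[2]) %% box[2],
      z = c(Ow[3], H1[3], H2[3]) %% box[3],
      element = c("O", "H", "H"),
      role = c("donor-heavy+acceptor", "donor-H", "donor-H"),
      parent_local = c(NA_integer_, 1L, 1L),
      mol = mol, class = "water"
    )
  }
  chain_site <- function(cand, Ow, dir, h_local) {
    pos <- (Ow + sample_bond_offset(dir)) %% box
    ch <- next_chain()
    cand <- dplyr::bind_rows(cand, tibble(
      x = pos[1], y = pos[2], z = pos[3], element = "O", role = "acceptor",
      parent_local = NA_integer_, mol = ch, class = "chain"
    ))
    idx <- nrow(cand)
    exempt <<- rbind(exempt, c(1L, -idx), c(h_local, -idx))
    planted <<- c(planted, list(list(dO = Ow, dH = Ow + .OH_BOND * dir,
                                     aO = pos, aH = NULL)))
    bonds <<- c(bonds, list(list(class = "water-chain", donor = mol,
                                 acceptor = cand$mol[idx])))
    cand
  }

  if (ws[w] == 2L) {
    s <- ws_partner[w]
    ki <- sites_w[1]; kj <- sites_w[2]
    pi_ <- small_O[[s]][ki, ]; pj <- small_O[[s]][kj, ]
    mid <- (pi_ + pj) / 2
    sep <- pj - pi_
    a <- sep / sqrt(sum(sep^2))
    h <- sqrt(.HB_DA^2 - sum(sep^2) / 4)
    pb <- perp_basis(a)
    phi <- runif(1, 0, 2 * pi)
    Ow <- mid + h * (cos(phi) * pb$u1 + sin(phi) * pb$u2)
    vi <- (pi_ - Ow) / sqrt(sum((pi_ - Ow)^2))
    vj <- (pj - Ow) / sqrt(sum((pj - Ow)^2))
    b <- vi + vj; b <- b / sqrt(sum(b^2))
    pp <- vi - sum(vi * b) * b; pp <- pp / sqrt(sum(pp^2))
    H1 <- Ow + .OH_BOND * (cos(hoh / 2) * b + sin(hoh / 2) * pp)
    H2 <- Ow + .OH_BOND * (cos(hoh / 2) * b - sin(hoh / 2) * pp)
    cand <- water_atoms(Ow, H1, H2)
    for (kk in c(ki, kj)) {
      oidx <- small_atom0[s] + kk
      hidx <- small_atom0[s] + 3L + kk
      exempt <- rbind(exempt, c(1L, oidx), c(2L, oidx), c(3L, oidx),
                      c(1L, hidx), c(2L, hidx), c(3L, hidx))
    }
    planted <- c(planted,
                 list(list(dO = Ow, dH = H1, aO = pi_, aH = small_H[[s]][ki, ]),
                      list(dO = Ow, dH = H2, aO = pj, aH = small_H[[s]][kj, ])))
    bonds <- c(bonds,
               list(list(class = "water-small", donor = mol, acceptor = id_small[s]),
                    list(class = "water-small", donor = mol, acceptor = id_small[s])))
  } else if (ws[w] == 1L) {
    s <- ws_partner[w]
    k <- sites_w[1]
    pa <- small_O[[s]][k, ]
    v <- rand_unit()
    Ow <- pa + runif(1, 2.65, 3.35) * v
    H1 <- Ow - .OH_BOND * v
    pb <- perp_basis(-v)
    phi <- runif(1, 0, 2 * pi)
    d2 <- cos(hoh) * (-v) + sin(hoh) * (cos(phi) * pb$u1 + sin(phi) * pb$u2)
    H2 <- Ow + .OH_BOND * d2
    cand <- water_atoms(Ow, H1, H2)
    oidx <- small_atom0[s] + k
    hidx <- small_atom0[s] + 3L + k
    exempt <- rbind(exempt, c(1L, oidx), c(2L, oidx), c(1L, hidx), c(2L, hidx))
    planted <- c(planted, list(list(dO = Ow, dH = H1, aO = pa,
                                    aH = small_H[[s]][k, ])))
    bonds <- c(bonds, list(list(class = "water-small", donor = mol,
                                acceptor = id_small[s])))
    if (wc[w] > 0) cand <- chain_site(cand, Ow, d2, 3L)
  } else {
    Ow <- runif(3) * box
    R <- rand_rotation()
    d1 <- drop(c(1, 0, 0) %*% t(R))
    d2 <- drop(c(cos(hoh), sin(hoh), 0) %*% t(R))
    H1 <- Ow + .OH_BOND * d1
    H2 <- Ow + .OH_BOND * d2
    cand <- water_atoms(Ow, H1, H2)
    if (wc[w] >= 1L) cand <- chain_site(cand, Ow, d1, 2L)
    if (wc[w] >= 2L) cand <- chain_site(cand, Ow, d2, 3L)
  }
  list(cand = cand, exempt = exempt, planted = planted, bonds = bonds)
}

realized_from_log <- function(planted, id_small, id_water) {
  out <- list()
  donor_counts <- function(ids, class) {
    sel <- planted[planted$class == class, , drop = FALSE]
    setNames(as.integer(table(factor(sel$donor_molecule, levels = ids))), ids)
  }
  if (length(id_small)) {
    sel <- planted[planted$class == "small-small", , drop = FALSE]
    out[["small-small"]] <- setNames(
      as.integer(table(factor(sel$donor_molecule, levels = id_small))) +
        as.integer(table(factor(sel$acceptor_molecule, levels = id_small))),
      id_small
    )
    out[["small-chain"]] <- donor_counts(id_small, "small-chain")
  }
  if (length(id_water)) {
    out[["water-chain"]] <- donor_counts(id_water, "water-chain")
    out[["water-small"]] <- donor_counts(id_water, "water-small")
  }
  out
}

# re-measure the finished box and require exact agreement with the plan
verify_planted <- function(cfg, plan) {
  bonds <- detect_hbonds(cfg)
  planted <- attr(cfg, "planted")
  if (nrow(bonds) != nrow(planted)) return(FALSE)
  realized <- attr(cfg, "realized_counts")
  topo <- cfg$atoms
  id_small <- sort(unique(topo$molecule_id[topo$molecule_class == "small"]))
  id_water <- sort(unique(topo$molecule_id[topo$molecule_class == "water"]))
  measure <- function(donor_class, acceptor_class, ids, direction) {
    b <- bonds[bonds$donor_class == donor_class &
                 bonds$acceptor_class == acceptor_class, , drop = FALSE]
    cnt <- as.integer(table(factor(b$donor_molecule, levels = ids)))
    if (direction == "either") {
      cnt <- cnt + as.integer(table(factor(b$acceptor_molecule, levels = ids)))
    }
    cnt
  }
  ok <- TRUE
  if (length(id_small)) {
    ok <- ok &&
      identical(sort(measure("small", "small", id_small, "either")),
                sort(unname(realized[["small-small"]]))) &&
      identical(sort(measure("small", "chain", id_small, "as-donor")),
                sort(unname(realized[["small-chain"]])))
  }
  if (length(id_water)) {
    ok <- ok &&
      identical(sort(measure("water", "chain", id_water, "as-donor")),
                sort(unname(realized[["water-chain"]]))) &&
      identical(sort(measure("water", "small", id_water, "as-donor")),
                sort(unname(realized[["water-small"]])))
  }
  ok
}
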