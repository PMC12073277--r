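# Independent brute-force oracles used to cross-check the vectorised
# implementations. Deliberately written as plain triple loops over a
# different code path.

min_image_d <- function(p, q, box) {
  d <- q - p
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# triple-loop hydrogen-bond detection oracle
oracle_hbonds <- function(config, d_max = 3.5, angle_max = 30) {
  atoms <- config$atoms
  box <- config$box
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  has_role <- function(r, what) {
    vapply(strsplit(r, "+", fixed = TRUE), function(z) what %in% z, logical(1))
  }
  h_idx <- which(has_role(atoms$site_role, "donor-H"))
  a_idx <- which(has_role(atoms$site_role, "acceptor"))
  out <- list()
  for (h in h_idx) {
    d <- atoms$parent[h]
    for (a in a_idx) {
      if (a == d || a == h) next
      if (atoms$molecule_id[a] == atoms$molecule_id[d]) next
      dist <- min_image_d(xyz[d, ], xyz[a, ], box)
      if (dist >= d_max) next
      v1 <- xyz[h, ] - xyz[d, ]
      v1 <- v1 - box * round(v1 / box)
      v2 <- xyz[a, ] - xyz[d, ]
      v2 <- v2 - box * round(v2 / box)
      ang <- acos(max(min(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), 1), -1)) * 180 / pi
      if (ang < angle_max) {
        out[[length(out) + 1L]] <- c(donor = d, h = h, acceptor = a)
      }
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3))
  do.call(rbind, out)
}

# union-find connected components over a molecule-level edge list
oracle_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1])
      b <- find(edges[e, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(table(factor(roots, levels = unique(roots))))
}

# two-plane-normal dihedral oracle (no atan2 formulation)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  ang <- acos(max(min(sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2)), 1), -1)) * 180 / pi
  # sign from the scalar triple product
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# random box of simple hydroxyl-bearing molecules for detection tests
random_oh_config <- function(n_mol = 50, box = c(24, 24, 24), seed = 1) {
  withr::with_seed(seed, {
    atoms <- NULL
    for (m in seq_len(n_mol)) {
      o <- runif(3) * box
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      h <- o + 0.96 * u
      atoms <- rbind(atoms, data.frame(
        element = c("O", "H"), x = c(o[1], h[1]), y = c(o[2], h[2]),
        z = c(o[3], h[3]), molecule_id = m, molecule_class = "small",
        site_role = c("donor-heavy+acceptor", "donor-H"),
        parent = c(NA_integer_, 2L * m - 1L)
      ))
    }
    as_config(atoms, box)
  })
}
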