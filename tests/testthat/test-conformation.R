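test_that("wrap_angle maps onto the half-open interval (-180, 180]", {
  expect_equal(wrap_angle(180), 180)
  expect_equal(wrap_angle(-180), 180)
  expect_equal(wrap_angle(370), 10)
  expect_equal(wrap_angle(c(0, -190, 540)), c(0, 170, 180))
  expect_error(wrap_angle(Inf), "finite")
  expect_error(wrap_angle("a"), "numeric")
  # NA marks undefined terminal torsions and passes through
  expect_true(is.na(wrap_angle(NA_real_)))
})

test_that("torsion_chain enforces the terminal-NA convention and bounds", {
  ch <- torsion_chain(phi = c(NA, -57, -57), psi = c(-47, -47, NA),
                      omega = c(180, 180, NA))
  expect_s3_class(ch, "torsion_chain")
  expect_equal(nrow(ch), 3)
  expect_error(torsion_chain(phi = NA_real_, psi = NA_real_), "2 residues")
  expect_error(torsion_chain(phi = c(0, 1), psi = c(1, NA)), "undefined")
  expect_error(torsion_chain(phi = c(NA, 1), psi = c(1, 2)), "undefined")
  expect_error(torsion_chain(phi = c(NA, NA, 1), psi = c(1, 1, NA)),
               "non-NA")
})

test_that("dihedral_angle matches the plane-normal oracle and conventions", {
  p1 <- c(0, 0, 0); p2 <- c(1, 0, 0); p3 <- c(1, 1, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(0, 1, 0)), 0)    # cis
  expect_equal(dihedral_angle(p1, p2, p3, c(2, 1, 0)), 180)  # trans
  withr::with_seed(42, {
    for (k in 1:200) {
      pts <- matrix(rnorm(12), 4, 3)
      got <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      want <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
      expect_lt(circ_abs(got, want), 1e-9)
    }
  })
  expect_error(dihedral_angle(p1, p2, c(2, 0, 0), c(3, 0, 0)), "ollinear")
})

test_that("extended chain reproduces the trans peptide CA-CA distance", {
  # independent 2D trigonometric construction of the trans peptide unit:
  # CA1 and CA2 in the plane, relative to the C-N bond along +x
  b_ca_c <- 1.525; b_c_n <- 1.329; b_n_ca <- 1.458
  a_ca_c_n <- 116.2 * pi / 180; a_c_n_ca <- 121.7 * pi / 180
  CA1 <- c(b_ca_c * cos(a_ca_c_n), b_ca_c * sin(a_ca_c_n))
  N2 <- c(b_c_n, 0)
  CA2 <- N2 + b_n_ca * c(cos(pi - a_c_n_ca), -sin(pi - a_c_n_ca))
  expected <- sqrt(sum((CA1 - CA2)^2))

  ch <- torsion_chain(phi = c(NA, rep(180, 4)), psi = c(rep(180, 4), NA))
  s <- torsions_to_cartesian(ch)
  ca <- as.matrix(as.data.frame(s[s$atom == "CA", c("x", "y", "z")]))
  d <- sqrt(rowSums(diff(ca)^2))
  expect_equal(d, rep(expected, 4), tolerance = 1e-6)
  expect_equal(expected, 3.80, tolerance = 0.005)
})

test_that("first three atoms define the canonical frame", {
  ch <- random_chain(6, seed = 3)
  s <- torsions_to_cartesian(ch)
  m <- as.matrix(as.data.frame(s[s$atom %in% c("N", "CA", "C"),
                                 c("x", "y", "z")]))
  expect_equal(m[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(m[2, 2:3], c(0, 0), ignore_attr = TRUE)   # CA1 on +x
  expect_gt(m[2, 1], 0)
  expect_equal(unname(m[3, 3]), 0)                       # C1 in xy-plane
})

test_that("torsion round trip is exact and bond geometry matches the input", {
  geom <- geometry_params()
  withr::with_seed(7, {
    for (k in 1:100) {
      L <- sample(3:30, 1)
      ch <- random_chain(L)
      s <- torsions_to_cartesian(ch, geom)
      ch2 <- cartesian_to_torsions(s)
      expect_lt(max(circ_abs(ch$phi[-1], ch2$phi[-1]),
                    circ_abs(ch$psi[-L], ch2$psi[-L]),
                    circ_abs(ch$omega[-L], ch2$omega[-L])), 1e-6)
      # all emitted angles respect the interval invariant
      ang <- c(ch2$phi[-1], ch2$psi[-L], ch2$omega[-L])
      expect_true(all(ang > -180 & ang <= 180))
    }
  })
  # bond lengths equal the geometry parameters exactly (up to fp)
  ch <- random_chain(8, seed = 9)
  s <- torsions_to_cartesian(ch, geom)
  m <- as.matrix(as.data.frame(s[s$atom %in% c("N", "CA", "C"),
                                 c("x", "y", "z")]))
  d <- sqrt(rowSums(diff(m)^2))
  expect_equal(d, rep(c(geom$b_n_ca, geom$b_ca_c, geom$b_c_n), 8)[1:23],
               tolerance = 1e-9)
})

test_that("measured torsions are invariant under rigid-body motion", {
  ch <- random_chain(10, seed = 11)
  s <- torsions_to_cartesian(ch)
  withr::with_seed(12, {
    s2 <- transform_structure(s, random_rotation(), rnorm(3, 0, 50))
  })
  ch2 <- cartesian_to_torsions(s2)
  expect_lt(max(circ_abs(ch$phi[-1], ch2$phi[-1]),
                circ_abs(ch$psi[-10], ch2$psi[-10])), 1e-9)
})

test_that("cartesian_to_torsions reports missing backbone atoms", {
  ch <- random_chain(4, seed = 5)
  s <- torsions_to_cartesian(ch)
  s_noN <- s[!(s$residue == 2 & s$atom == "N"), ]
  expect_error(cartesian_to_torsions(s_noN), "N for residue")
})

test_that("perturb_chain adds seeded Gaussian noise to phi/psi only", {
  ch <- random_chain(12, seed = 21)
  expect_equal(perturb_chain(ch, 0, seed = 1), ch)
  p1 <- perturb_chain(ch, 5, seed = 99)
  p2 <- perturb_chain(ch, 5, seed = 99)
  expect_equal(p1, p2)
  expect_false(isTRUE(all.equal(p1$phi[-1], ch$phi[-1])))
  expect_equal(p1$omega, ch$omega)  # omega untouched by default
  p3 <- perturb_chain(ch, 5, seed = 99, include_omega = TRUE)
  expect_false(isTRUE(all.equal(p3$omega[-12], ch$omega[-12])))
  expect_error(perturb_chain(ch, -1), "non-negative")
  # law of large numbers: empirical sd of applied deltas within 5%
  big <- torsion_chain(phi = c(NA, rep(0, 5000)), psi = c(rep(0, 5000), NA))
  pb <- perturb_chain(big, 5, seed = 4)
  deltas <- c(wrap_angle(pb$phi[-1]), wrap_angle(pb$psi[-5001]))
  expect_lt(abs(sd(deltas) - 5) / 5, 0.05)
})

test_that("geometry_params validates physical ranges", {
  expect_error(geometry_params(b_n_ca = 0.2), "0.5, 3.0")
  expect_error(geometry_params(a_n_ca_c = 45), "60, 180")
})
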