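test_that("sequence power laws give the expected peptide sizes", {
  # 13-residue helical tag: ~1.0 nm
  expect_equal(rh_from_sequence_length(13), 1.0, tolerance = 0.1)
  expect_equal(rh_from_sequence_length(1), 0.475)
  n <- 1:400
  expect_true(all(diff(rh_from_sequence_length(n)) > 0))
  expect_true(all(diff(rh_from_sequence_length(n, "disordered")) > 0))
  # disordered chains are larger than folded ones at equal length
  expect_gt(rh_from_sequence_length(100, "disordered"),
            rh_from_sequence_length(100, "folded"))
  expect_error(rh_from_sequence_length(0), ">= 1")
})

test_that("Kirkwood predictor reproduces closed-form bead results", {
  one <- structure_model(matrix(0, 1, 3), "C")
  a <- (1.70 + 1.1) / 10
  expect_equal(rh_from_structure(one, hydration_shell = 1.1), a)
  # two beads radius a, separation d: Rh = 2 a d / (a + d)
  for (d_A in c(6, 10, 50, 1000)) {
    two <- structure_model(rbind(c(0, 0, 0), c(0, 0, d_A)), "C")
    d <- d_A / 10
    expect_equal(rh_from_structure(two, hydration_shell = 1.1),
                 2 * a * d / (a + d), tolerance = 1e-12)
  }
  # far-separated pair tends to 2a
  far <- structure_model(rbind(c(0, 0, 0), c(0, 0, 1e6)), "C")
  expect_equal(rh_from_structure(far, hydration_shell = 1.1), 2 * a,
               tolerance = 1e-4)
})

test_that("dumbbell at contact is one third larger than a single bead", {
  a_A <- 1.70 + 1.1
  one <- structure_model(matrix(0, 1, 3), "C")
  dumb <- structure_model(rbind(c(0, 0, 0), c(0, 0, 2 * a_A)), "C")
  out <- predicted_complex_change(one, dumb, hydration_shell = 1.1)
  expect_equal(out$pct_change, 100 / 3, tolerance = 1e-9)
  # identical structures: zero change
  expect_equal(predicted_complex_change(dumb, dumb,
                                        hydration_shell = 1.1)$pct_change, 0)
})

test_that("prediction is invariant under rigid motion and grows with additions", {
  set.seed(5)
  xyz <- matrix(rnorm(30, sd = 5), 10, 3)
  s1 <- structure_model(xyz, "C")
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- structure_model(sweep(xyz %*% R, 2, c(3, -7, 11), "+"), "C")
  expect_lt(rel_err(rh_from_structure(s2), rh_from_structure(s1)), 1e-10)
  # appending a well-separated bead to a chain never shrinks the radius
  chain <- t(vapply(0:5, function(i) c(20 * i, 0, 0), numeric(3)))
  rhs <- vapply(2:6, function(k)
    rh_from_structure(structure_model(chain[1:k, ], "C")), numeric(1))
  expect_true(all(diff(rhs) > 0))
})

test_that("calibrated helix prediction agrees with the sequence power law", {
  hel <- rh_from_structure(ideal_helix(13), mode = "calpha")
  expect_lt(abs(hel / rh_from_sequence_length(13) - 1), 0.1)
  # a bound partner strictly containing the target's atoms grows the radius
  target <- ideal_helix(13)
  complex_ <- structure_model(rbind(target$xyz,
                                    sweep(target$xyz, 2, c(12, 0, 0), "+")))
  out <- predicted_complex_change(target, complex_, mode = "calpha")
  expect_gt(out$pct_change, 0)
  # a modest predicted change (< 2x the 10% threshold) recommends the
  # statistical rule; the +33% dumbbell recommends the plain threshold
  expect_equal(out$recommended_rule, "dunnett")
  a_A <- 1.70 + 1.1
  one <- structure_model(matrix(0, 1, 3), "C")
  dumb <- structure_model(rbind(c(0, 0, 0), c(0, 0, 2 * a_A)), "C")
  expect_equal(predicted_complex_change(one, dumb,
                 hydration_shell = 1.1)$recommended_rule, "threshold")
})

test_that("PDB files round-trip into structure models", {
  path <- withr::local_tempfile(fileext = ".pdb")
  hx <- ideal_helix(8)
  lines <- vapply(seq_len(8), function(i)
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, hx$xyz[i, 1], hx$xyz[i, 2], hx$xyz[i, 3]), character(1))
  writeLines(c(lines, "END"), path)
  sm <- read_structure_pdb(path, calpha_only = TRUE)
  expect_equal(nrow(sm$xyz), 8)
  expect_equal(sm$xyz, hx$xyz, tolerance = 1e-3)
  expect_equal(rh_from_structure(sm, mode = "calpha"),
               rh_from_structure(hx, mode = "calpha"), tolerance = 1e-3)
  expect_error(read_structure_pdb(path, chain = "Z"), "no matching atoms")
})
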