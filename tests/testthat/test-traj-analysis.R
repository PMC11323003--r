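test_that("frame construction validates and wraps positions", {
  fr <- frame(rbind(c(-1, 2, 3), c(11, 2, 3)), c("MG", "CL"), c(2, -1),
              c(10, 10, 10))
  expect_true(all(fr$positions >= 0 & fr$positions < 10))
  expect_equal(fr$positions[1, 1], 9)
  expect_error(frame(rbind(c(1, 2, 3)), c("A", "B"), 1, c(5, 5, 5)),
               "lengths differ")
  expect_error(frame(rbind(c(1, 2, 3)), "A", 1, c(5, -1, 5)), "positive")
})

test_that("concentration profile closes exactly on particle counts", {
  set.seed(2)
  box <- c(8, 4, 4)
  n <- 400
  fr <- frame(cbind(runif(n, 0, 8), runif(n, 0, 4), runif(n, 0, 4)),
              rep("MG", n), rep(2, n), box)
  p <- concentration_profile(fr, "MG", axis = "x", bin_width = 0.5)
  v_bin <- p$bin_width * 4 * 4
  # Sum over bins of c * V * N_A returns the exact count (closure identity)
  counts <- p$values * 6.02214076e23 * v_bin * 1e-24
  expect_equal(sum(counts), n, tolerance = 1e-9)
  # uniform box: each bin within 3 sigma of Poisson counting noise
  lambda <- n / length(p$values)
  expect_true(all(abs(counts - lambda) < 3 * sqrt(lambda) + 1e-9))
})

test_that("single-occupied-bin profile recovers the count exactly", {
  box <- c(10, 5, 5)
  m <- 17
  pos <- cbind(rep(3.1, m), runif(m, 0, 5), runif(m, 0, 5))
  fr <- frame(pos, rep("CL", m), rep(-1, m), box)
  p <- concentration_profile(fr, "CL", axis = "x", bin_width = 1)
  v_bin <- p$bin_width * 25
  counts <- p$values * 6.02214076e23 * v_bin * 1e-24
  expect_equal(sum(counts > 0.5), 1L)
  expect_equal(max(counts), m, tolerance = 1e-9)
  expect_error(concentration_profile(fr, "MG"), "available")
})

test_that("synthetic MgCl2 box recovers the target concentration", {
  rec <- system_recipe()
  fr <- place_ions(rec, NULL, mode = "uniform", seed = 9)
  p <- concentration_profile(fr, "MG", axis = "x", bin_width = 2)
  expect_equal(mean(p$values), 0.05, tolerance = 0.15)
})

test_that("shell net charge: bare DNA, decomposition, and whole-box limits", {
  rec <- system_recipe(box = c(24, 10, 6.8))
  dna <- build_scaffold(rec, membranes = FALSE)
  # park mobile ions far from the DNA (> 1 nm from any site, near the box
  # x-edge) so the 10 A shell sees only the duplexes
  n_mg <- 38; n_cl <- 2 * n_mg - 76
  set.seed(1)
  ion_pos <- cbind(runif(n_mg + n_cl, 0, 2), runif(n_mg + n_cl, 0, 10),
                   runif(n_mg + n_cl, 0, 6.8))
  fr <- frame(rbind(as.matrix(dna[, 1:3]), ion_pos),
              c(dna$species, rep(c("MG", "CL"), c(n_mg, n_cl))),
              c(dna$charge, rep(c(2, -1), c(n_mg, n_cl))),
              rec$box)
  sh <- shell_net_charge(fr, "DNA_P", cutoff = 1.0)
  expect_equal(sh$Q_T, -76)
  expect_equal(sum(sh$by_species), sh$Q_T, tolerance = 1e-12)
  # cutoff covering the whole box -> total (zero) system charge
  sh_all <- shell_net_charge(fr, "DNA_P", cutoff = sqrt(sum(rec$box^2)))
  expect_equal(sh_all$Q_T, 0)
  expect_equal(sh_all$n_in_shell, n_particles(fr))
})

test_that("zero-sum shell built by construction reports Q_T = 0", {
  fr <- frame(rbind(c(5, 5, 5), c(5.3, 5, 5), c(5, 5.3, 5)),
              c("DNA_P", "MG", "CL"), c(-1, 2, -1), c(10, 10, 10))
  expect_equal(shell_net_charge(fr, "DNA_P", 0.5)$Q_T, 0)
})

test_that("coordination count matches construction and the pair-scan oracle", {
  # 18 Mg placed within the cutoff of DNA sites, 22 beyond; 40 bp
  set.seed(3)
  dna <- cbind(runif(10, 4, 6), runif(10, 4, 6), runif(10, 4, 6))
  near <- dna[sample(1:10, 18, replace = TRUE), ] +
    matrix(runif(54, -0.2, 0.2), 18)
  far <- cbind(runif(22, 0, 1), runif(22, 0, 1), runif(22, 0, 1))
  fr <- frame(rbind(dna, near, far),
              rep(c("DNA_P", "MG", "MG"), c(10, 18, 22)),
              rep(c(-1, 2, 2), c(10, 18, 22)), c(12, 12, 12))
  expect_equal(coordination_count(fr, "DNA_P", "MG", cutoff = 0.5,
                                  normalize_per = 40), 18 / 40)
  expect_equal(coordination_count(fr, "DNA_P", "MG", cutoff = 0,
                                  normalize_per = 40), 0)
  # random frame against the O(N^2) oracle
  rf <- random_frame(n = 80, seed = 21)
  got <- coordination_count(rf, "DNA_P", "MG", cutoff = 0.9)
  expect_equal(got, oracle_count_within(rf, "DNA_P", "MG", 0.9))
})

test_that("contact census resolves direct contacts and Mg bridges", {
  box <- c(10, 10, 10)
  # Mg midway between a PC_OP and a DNA_P: bridge, no direct contact
  fr1 <- frame(rbind(c(5, 5, 5), c(5.4, 5, 5), c(5.8, 5, 5)),
               c("PC_OP", "MG", "DNA_P"), c(-1, 2, -1), box)
  expect_equal(contact_census(fr1), list(n_direct = 0L, n_bridge = 1L))
  # TAP_N adjacent to DNA_P, no Mg: direct contact only
  fr2 <- frame(rbind(c(5, 5, 5), c(5.4, 5, 5)),
               c("TAP_N", "DNA_P"), c(1, -1), box)
  expect_equal(contact_census(fr2), list(n_direct = 1L, n_bridge = 0L))
  # randomized frame against brute-force recount
  rf <- random_frame(n = 120, seed = 8)
  cc <- contact_census(rf)
  want_direct <- oracle_count_within(rf, "DNA_P", c("TAP_N", "PC_N"), 0.6)
  mg <- which(rf$species == "MG")
  want_bridge <- 0
  for (i in mg) {
    a <- any(sapply(which(rf$species %in% c("PC_OP", "PC_O", "TAP_O")),
                    function(j) oracle_min_image_dist(rf$positions[i, ],
                      rf$positions[j, ], rf$box) <= 0.5))
    b <- any(sapply(which(rf$species == "DNA_P"),
                    function(j) oracle_min_image_dist(rf$positions[i, ],
                      rf$positions[j, ], rf$box) <= 0.5))
    if (a && b) want_bridge <- want_bridge + 1
  }
  expect_equal(cc$n_direct, as.integer(want_direct))
  expect_equal(cc$n_bridge, as.integer(want_bridge))
})

test_that("censuses are invariant under rigid translation with wrapping", {
  rf <- random_frame(n = 100, seed = 13)
  shift <- c(1.7, -2.3, 0.9)
  rf2 <- frame(sweep(rf$positions, 2, shift, "+"), rf$species, rf$charges,
               rf$box)
  expect_equal(contact_census(rf), contact_census(rf2))
  expect_equal(shell_net_charge(rf, "DNA_P", 0.8)$Q_T,
               shell_net_charge(rf2, "DNA_P", 0.8)$Q_T)
  expect_equal(coordination_count(rf, "DNA_P", "MG", 0.7),
               coordination_count(rf2, "DNA_P", "MG", 0.7))
})

test_that("g(r) is flat for an ideal gas and matches the histogram oracle", {
  set.seed(17)
  box <- c(6, 6, 6)
  n <- 350
  fr <- frame(cbind(runif(n, 0, 6), runif(n, 0, 6), runif(n, 0, 6)),
              rep(c("MG", "CL"), c(175, 175)),
              rep(c(2, -1), c(175, 175)), box)
  g <- radial_distribution(fr, "MG", "CL", r_max = 2.9, bin_width = 0.2)
  expect_lt(abs(mean(g$values) - 1), 0.1)
  edges <- seq(0, g$bin_width * length(g$values), by = g$bin_width)
  h <- oracle_rdf_hist(fr, "MG", "CL", edges)
  shell <- 4 / 3 * pi * diff(edges^3)
  want <- h / (175 * 175 * shell / prod(box))
  expect_equal(g$values, want, tolerance = 1e-9)
  expect_error(radial_distribution(fr, "MG", "CL", r_max = 4), "half")
})

test_that("two fixed particles give a single g(r) peak at their separation", {
  fr <- frame(rbind(c(1, 1, 1), c(1, 1, 2.53)), c("MG", "MG"), c(2, 2),
              c(8, 8, 8))
  g <- radial_distribution(fr, "MG", "MG", r_max = 3.5, bin_width = 0.1)
  expect_equal(sum(g$values > 0), 1L)
  expect_equal(g$bin_centers[which.max(g$values)], 1.55, tolerance = 1e-9)
})

test_that("mean ion separation: exact cases and the all-pairs oracle", {
  fr2 <- frame(rbind(c(1, 1, 1), c(4, 1, 1)), c("MG", "MG"), c(2, 2),
               c(10, 10, 10))
  expect_equal(mean_ion_separation(fr2, "MG"), 3.0)
  # regular 1-D lattice of spacing a
  a <- 1.25
  z <- (0:7) * a
  frl <- frame(cbind(rep(1, 8), rep(1, 8), z), rep("CL", 8), rep(-1, 8),
               c(5, 5, 10))
  expect_equal(mean_ion_separation(frl, "CL"), a)
  # random frame vs brute-force nearest neighbors
  rf <- random_frame(n = 50, seed = 31)
  sel <- which(rf$species == "MG")
  nn <- sapply(sel, function(i) {
    min(sapply(setdiff(sel, i), function(j) {
      oracle_min_image_dist(rf$positions[i, ], rf$positions[j, ], rf$box)
    }))
  })
  expect_equal(mean_ion_separation(rf, "MG"), mean(nn), tolerance = 1e-12)
  expect_error(mean_ion_separation(fr2, "MG",
                                   region = list(axis = "x", min = 0,
                                                 max = 0.5)),
               "fewer than 2")
})

test_that("charge compensation fraction is a simple percentage", {
  expect_equal(round(charge_compensation(36.4, -76)), 48)
  expect_equal(charge_compensation(38, 76), 50)
  expect_error(charge_compensation(1, 0), "nonzero")
})
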