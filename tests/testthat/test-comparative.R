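test_that("COM normalisation anchors 0 at the acetabulum and 1 at the glenoid", {
  tab <- flat_scaling_table(k = 1)
  hom <- density_scheme("custom", homogeneous_value = 1000)
  mk <- function(center) {
    m <- box_skeleton(list(list(class = "torso", center = center,
                                size = c(0.2, 0.2, 0.2))),
                      glenoid = c(2, 0, 0.5))
    list(m = m, b = body_mass_props(m, expansion_policy("NAS_isometric"),
                                    tab, hom))
  }
  at_acet <- mk(c(0, 0, 0))
  expect_equal(normalize_com(at_acet$b, at_acet$m)$com_ap_ga, 0,
               tolerance = 1e-12)
  at_glen <- mk(c(2, 0, 0))
  expect_equal(normalize_com(at_glen$b, at_glen$m)$com_ap_ga, 1,
               tolerance = 1e-12)

  # mass^(1/3) normalisation: 1000 kg, COM x = 0.5 -> 0.05
  mid <- mk(c(0.5, 0, 0))
  mid$b$total_mass <- 1000  # exact round mass for the arithmetic check
  expect_equal(normalize_com(mid$b, mid$m)$com_ap_m13, 0.05, tolerance = 1e-12)

  # translation invariance: the frame is re-origined at the acetabulum
  m_shift <- box_skeleton(list(list(class = "torso", center = c(10.5, 3, -2),
                                    size = c(0.2, 0.2, 0.2))),
                          acetabulum = c(10, 3, -2), glenoid = c(12, 3, -1.5))
  b_shift <- body_mass_props(m_shift, expansion_policy("NAS_isometric"), tab, hom)
  expect_equal(normalize_com(b_shift, m_shift)$com_ap_ga,
               normalize_com(mid$b, mid$m)$com_ap_ga, tolerance = 1e-9)

  # DV-degenerate taxa get NA for the GA-normalised DV coordinate
  m_deg <- box_skeleton(list(list(class = "torso", center = c(0.5, 0, 0.3),
                                  size = c(0.2, 0.2, 0.2))),
                        glenoid = c(1, 0, 0))
  b_deg <- body_mass_props(m_deg, expansion_policy("NAS_isometric"), tab, hom)
  rec <- normalize_com(b_deg, m_deg)
  expect_true(rec$dv_degenerate)
  expect_true(is.na(rec$com_dv_ga))
  expect_false(is.na(rec$com_dv_m13))
})

test_that("stylopodial masses follow the log-linear equation with mPPE bounds", {
  sm <- stylopodial_model("bipedal", slope = 1, intercept = 0, mppe = 0.25)
  est <- stylopodial_mass(10, sm)
  expect_equal(est$mass, 10)
  expect_equal(est$mass_lower, 7.5)
  expect_equal(est$mass_upper, 12.5)

  # doubling C multiplies mass by 2^slope
  sm2 <- stylopodial_model("quadrupedal", slope = 2.75, intercept = -1.1)
  expect_equal(stylopodial_mass(400, sm2)$mass / stylopodial_mass(200, sm2)$mass,
               2^2.75, tolerance = 1e-12)

  # brute-force log-space evaluation
  C <- c(33.7, 512, 1800.4)
  expect_equal(stylopodial_mass(C, sm2)$mass,
               vapply(C, function(ci) 10^(-1.1 + 2.75 * log10(ci)), 0),
               tolerance = 1e-12)

  expect_error(stylopodial_model("bipedal"), "config")
  expect_error(stylopodial_model("bipedal", slope = -1, intercept = 0),
               "positive")
  expect_error(stylopodial_mass(-5, sm), "positive")
})

test_that("Spearman's rho matches a mid-rank brute force and is monotone-invariant", {
  x <- c(3, 1, 4, 1, 5, 9)
  y <- c(2, 7, 1, 8, 2, 8)   # ties in both
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, 0)
  }
  brute <- stats::cor(midrank(x), midrank(y))
  expect_equal(spearman_rho(x, y), brute, tolerance = 1e-12)

  expect_equal(spearman_rho(1:7, (1:7)^3), 1)
  expect_equal(spearman_rho(1:7, rev(1:7)), -1)
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b))
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("AICc has the closed form and tends to AIC for large n", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  ll <- -12.3
  expect_equal(aicc(ll, 3, 1e9), -2 * ll + 2 * 3, tolerance = 1e-6)
  expect_error(aicc(0, 3, 4), "n <= k \\+ 1")
})

test_that("OLS fits recover exact lines and flag allometry verdicts", {
  x <- seq(0, 3, length.out = 12)
  f <- suppressWarnings(fit_allometry(2 * x + 1, x, method = "OLS", iso_slope = 1))
  expect_equal(f$slope, 2, tolerance = 1e-9)
  expect_equal(f$intercept, 1, tolerance = 1e-9)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
  expect_equal(f$verdict, "positive")

  set.seed(8)
  y <- 1 / 3 * x + rnorm(12, sd = 0.05)
  f2 <- fit_allometry(y, x, method = "OLS", iso_slope = 1 / 3)
  expect_equal(f2$verdict, "isometry-within-CI")
  f3 <- suppressWarnings(fit_allometry(-x + 5, x, method = "OLS", iso_slope = 1))
  expect_equal(f3$verdict, "negative")
  expect_error(fit_allometry(1:5, rep(1, 5), method = "OLS"), "singular")
})

test_that("PGLS equals OLS on a star phylogeny and matches the whitened-GLS oracle", {
  star <- ape::stree(10, type = "star")
  star$edge.length <- rep(1, 10)
  set.seed(13)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10, sd = 0.3)
  names(x) <- names(y) <- star$tip.label
  f_ols <- fit_allometry(y, x, method = "OLS")
  f_pgls <- fit_allometry(y, x, tree = star, method = "PGLS")
  expect_equal(f_pgls$slope, f_ols$slope, tolerance = 1e-9)
  expect_equal(f_pgls$intercept, f_ols$intercept, tolerance = 1e-9)

  # structured tree: coefficients match an explicit whitened-GLS solve
  set.seed(14)
  tr <- ape::rphylo(16, birth = 1, death = 0)
  xt <- simulate_brownian(tr, 1, seed = 15)
  yt <- 0.8 * xt + simulate_brownian(tr, 0.2, seed = 16)
  f <- fit_allometry(yt, xt, tree = tr, method = "PGLS", iso_slope = 1)
  oracle <- pgls_oracle(tr, yt[tr$tip.label], xt[tr$tip.label], tr$tip.label)
  expect_equal(f$intercept, oracle[1L], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(f$slope, oracle[2L], tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(f$slope_ci[1L] < f$slope && f$slope < f$slope_ci[2L])
  expect_true(is.finite(f$aicc))
  expect_equal(f$aicc, aicc(f$loglik, 3, 16))
})

test_that("ancestral states solve the Brownian GLS system", {
  # two tips, equal branches: root is the arithmetic mean
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  anc <- ancestral_states(t2, c(a = 0, b = 4))
  expect_equal(unname(anc), 2)

  # constant tips reconstruct constant everywhere
  set.seed(20)
  tr <- ape::rphylo(16, 1, 0)
  anc_c <- ancestral_states(tr, setNames(rep(3.3, 16), tr$tip.label))
  expect_equal(unname(anc_c), rep(3.3, tr$Nnode), tolerance = 1e-9)

  # 16-tip random tree: matches the explicit linear-system oracle
  x <- simulate_brownian(tr, 1, root_value = 2, seed = 21)
  anc_x <- ancestral_states(tr, x)
  oracle <- anc_gls_oracle(tr, x)
  expect_equal(unname(anc_x), unname(oracle[names(anc_x)]), tolerance = 1e-8)

  # linearity: reconstruct(a v + b) = a reconstruct(v) + b
  anc_lin <- ancestral_states(tr, 2.5 * x + 1)
  expect_equal(unname(anc_lin), unname(2.5 * anc_x + 1), tolerance = 1e-8)

  # zero-length terminal branches are epsilon-substituted with a warning
  tr0 <- tr
  term <- tr0$edge[, 2L] <= 16
  tr0$edge.length[which(term)[1L]] <- 0
  expect_warning(ancestral_states(tr0, x), "epsilon")

  expect_error(ancestral_states(tr, x[-1]), "complete")
})

test_that("phylomorphospace couples observed tips with reconstructed ancestors", {
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  pm <- phylomorphospace(t2, c(a = 0, b = 2), c(a = 1, b = 3))
  expect_equal(nrow(pm$nodes), 3L)
  expect_equal(nrow(pm$edges), 2L)
  expect_equal(pm$nodes$x[pm$nodes$type == "internal"], 1)
  expect_equal(pm$nodes$y[pm$nodes$type == "internal"], 2)

  set.seed(30)
  tr <- ape::rphylo(12, 1, 0)
  tx <- simulate_brownian(tr, 1, seed = 31)
  ty <- simulate_brownian(tr, 1, seed = 32)
  pm1 <- phylomorphospace(tr, tx, ty)
  # node count = tips + internal nodes; permuting input order changes nothing
  expect_equal(nrow(pm1$nodes), 12 + tr$Nnode)
  perm <- sample(12)
  pm2 <- phylomorphospace(tr, tx[perm], ty[perm])
  expect_equal(pm2$nodes, pm1$nodes)
})
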