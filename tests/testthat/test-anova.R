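test_that("epsilon formula: identity covariance is spherical, rank-1 hits the lower bound", {
  expect_equal(gg_epsilon(matrix(2.5)), 1)           # k = 2: single contrast
  expect_equal(gg_epsilon(diag(4)), 1)               # sphericity
  expect_equal(gg_epsilon(diag(c(1, 0))), 0.5)       # (tr C)^2 / (2 tr C^2)
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  # bounds respected on random PSD matrices
  set.seed(21)
  for (i in 1:25) {
    d <- sample(2:6, 1)
    A <- matrix(rnorm(d * d), d)
    e <- gg_epsilon(crossprod(A))
    expect_gte(e, 1 / d)
    expect_lte(e, 1)
  }
})

test_that("two-way within decomposition reproduces aov's error strata", {
  set.seed(8)
  d <- expand.grid(patient_id = paste0("s", 1:7), direction = c("a", "b", "c", "d"),
                   eccentricity_deg = c(1, 2, 3))
  d$delta_iop <- rnorm(nrow(d)) + as.numeric(d$direction == "a")
  a <- rm_anova_within(d, within = c("direction", "eccentricity_deg"))
  ref <- summary(aov(delta_iop ~ direction * factor(eccentricity_deg) +
                       Error(patient_id / (direction * factor(eccentricity_deg))),
                     data = d))
  gets <- function(stratum) {
    s <- ref[[stratum]][[1]]
    list(SS = s[["Sum Sq"]], F = s[["F value"]][1], p = s[["Pr(>F)"]][1])
  }
  dir_ref <- gets("Error: patient_id:direction")
  expect_equal(a$SS[a$effect == "direction"], dir_ref$SS[1], tolerance = 1e-10)
  expect_equal(a$error_SS[a$effect == "direction"], dir_ref$SS[2], tolerance = 1e-10)
  expect_equal(a$F[a$effect == "direction"], dir_ref$F, tolerance = 1e-10)
  expect_equal(a$p[a$effect == "direction"], dir_ref$p, tolerance = 1e-10)
  int_ref <- gets("Error: patient_id:direction:factor(eccentricity_deg)")
  expect_equal(a$F[a$effect == "direction:eccentricity_deg"], int_ref$F,
               tolerance = 1e-10)
})

test_that("F equals t-squared on two-level single-factor designs (100 random tables)", {
  set.seed(100)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    d <- expand.grid(patient_id = paste0("s", seq_len(n)), cond = c("x", "y"))
    d$y <- rnorm(nrow(d))
    a <- rm_anova_within(d, dv = "y", within = "cond")
    tt <- paired_t(d$y[d$cond == "x"] - d$y[d$cond == "y"])
    expect_equal(a$F, tt$statistic^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p, tolerance = 1e-10)
    expect_equal(a$epsilon, 1)
  }
})

test_that("sums of squares decompose the total on random three-way tables", {
  set.seed(55)
  for (i in 1:5) {
    d <- expand.grid(patient_id = paste0("s", 1:6), direction = paste0("d", 1:4),
                     eccentricity_deg = 1:3, repetition = 1:2)
    d$delta_iop <- rnorm(nrow(d))
    a <- rm_anova_within(d)
    expect_equal(sum(a$SS) + sum(a$error_SS) + attr(a, "subject_SS"),
                 attr(a, "total_SS"), tolerance = 1e-9)
  }
})

test_that("epsilon approaches 1 under compound symmetry and its floor under rank-1 structure", {
  set.seed(66)
  n <- 400; k <- 4
  subj <- rnorm(n, 0, 2)
  d <- expand.grid(patient_id = seq_len(n), cond = paste0("c", 1:k))
  d$y <- subj[d$patient_id] + rnorm(nrow(d))     # compound-symmetric
  a <- rm_anova_within(d, dv = "y", within = "cond")
  expect_gt(a$epsilon, 0.95)

  # one dominant contrast direction: epsilon near 1/(k-1)
  d$y <- subj[d$patient_id] + rnorm(n)[d$patient_id] *
    (d$cond == "c1") * sqrt(2) * 10
  a2 <- rm_anova_within(d, dv = "y", within = "cond")
  expect_lt(a2$epsilon, 0.45)
  expect_gte(a2$epsilon, 1 / (k - 1))
})

test_that("missing cells are mean-imputed and counted; degenerate inputs error or flag", {
  d <- expand.grid(patient_id = paste0("s", 1:5), direction = c("a", "b"),
                   eccentricity_deg = 1, repetition = 1:3)
  d$delta_iop <- rnorm(nrow(d))
  miss <- d[-c(1, 8), ]
  a <- rm_anova_within(miss)
  expect_identical(attr(a, "n_imputed"), 2L)

  expect_error(rm_anova_within(d[d$patient_id == "s1", ]), "2 subjects")

  d$delta_iop <- 5                     # constant response
  a0 <- rm_anova_within(d)
  expect_true(all(a0$SS < 1e-20))
  expect_true(all(is.na(a0$F)))
})
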