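# crystal burden and the two-group statistics

test_that("burden recovers the generated crystal fraction", {
  sec <- generate_reflectance_section(crystal_fraction = 0.1, seed = 8L)
  b <- compute_burden(sec$image, sec$plaque_mask)
  true_pct <- 100 * sum(sec$crystal_mask) / sum(sec$plaque_mask)
  expect_lt(abs(b$burden_percent - true_pct), 0.2)

  # zero crystals and full coverage bound the scale
  sec0 <- generate_reflectance_section(crystal_fraction = 0, seed = 8L,
                                       noise_sd = 0)
  expect_equal(compute_burden(sec0$image, sec0$plaque_mask,
                              threshold = 100)$burden_percent, 0)
  sec1 <- generate_reflectance_section(crystal_fraction = 1, seed = 8L,
                                       noise_sd = 0)
  expect_equal(compute_burden(sec1$image, sec1$plaque_mask,
                              threshold = 100)$burden_percent, 100)

  # Otsu-within-plaque makes the burden scale invariant
  scaled <- intensity_image(sec$image$pixels * 37, sec$image$pixel_size_um,
                            "REFLECTANCE")
  expect_equal(compute_burden(scaled, sec$plaque_mask)$burden_percent,
               b$burden_percent)

  expect_error(compute_burden(sec$image, sec$plaque_mask & FALSE), "empty")
})

test_that("Mann-Whitney U matches exact enumeration and rank identities", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)  # 2 / choose(6, 3)

  same <- mann_whitney_u(c(2, 4, 9), c(2, 4, 9))
  expect_equal(same$p_value, 1)

  set.seed(40)
  for (k in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(1:8, n1, replace = TRUE)  # ties likely
    b <- sample(1:8, n2, replace = TRUE)
    u_ab <- mann_whitney_u(a, b)$statistic
    u_ba <- mann_whitney_u(b, a)$statistic
    expect_equal(u_ab + u_ba, n1 * n2)
  }

  # tie-free exact p agrees with wilcox.test's exact distribution
  set.seed(41)
  for (k in 1:15) {
    a <- rnorm(4); b <- rnorm(5)
    expect_equal(mann_whitney_u(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # normal approximation tracks the exact enumeration for n1, n2 >= 5
  # (the worst-case approximation error provably exceeds 0.02 for smaller
  # or more unbalanced groups)
  set.seed(42)
  for (k in 1:30) {
    n1 <- sample(5:6, 1); n2 <- sample(5:(12 - n1), 1)
    a <- rnorm(n1); b <- rnorm(n2)
    p_exact <- mann_whitney_u(a, b, exact = TRUE)$p_value
    p_norm <- mann_whitney_u(a, b, exact = FALSE)$p_value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }

  expect_error(mann_whitney_u(numeric(0), 1:3), "at least one")
})

test_that("t tests behave canonically", {
  eq <- t_test_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  # |t| grows monotonically with a constant shift
  a <- c(5.1, 5.9, 5.4, 5.6)
  tv <- vapply(c(0.2, 0.5, 1, 2), function(sh)
    abs(t_test_groups(a, a - sh)$statistic), numeric(1))
  expect_true(all(diff(tv) > 0))

  expect_error(t_test_groups(1:3, 1:4, paired = TRUE), "equal")
  expect_error(t_test_groups(1, 1:4), "n >= 2")
})

test_that("study comparison pools per-image metrics and finds directions", {
  # infected-like group: shorter needles, higher density
  set.seed(43)
  make_group <- function(n_img, len_scale, n_needles, seed0) {
    lapply(seq_len(n_img), function(i) {
      f <- generate_needle_field(needle_field_params(
        image_shape = c(192L, 192L), n_needles = n_needles + (i %% 3L),
        noise_sd = 5,
        length_um = list(family = "GAMMA", shape = 4, scale = 3 * len_scale,
                         min = 5 * len_scale, max = 15 * len_scale),
        seed = seed0 + i))
      run_morphometry(f$image)
    })
  }
  ctrl <- make_group(5, 1, 10L, 100)
  inf <- make_group(5, 0.67, 15L, 200)

  len_cmp <- compare_study(list(control = ctrl, infected = inf),
                           metric = "mean_length_um", method = "mann_whitney")
  expect_match(len_cmp$effect_direction, "higher in control")
  den_cmp <- compare_study(list(control = ctrl, infected = inf),
                           metric = "density_per_mm2", method = "t_unpaired")
  expect_match(den_cmp$effect_direction, "higher in infected")

  # per-animal aggregation reduces n to the animal count
  ids <- list(control = c("a1", "a1", "a1", "a2", "a2"),
              infected = c("b1", "b1", "b2", "b2", "b3"))
  agg <- compare_study(list(control = ctrl, infected = inf),
                       metric = "mean_length_um", method = "mann_whitney",
                       animal_ids = ids)
  expect_identical(agg$n_per_group, c(2L, 3L))

  expect_error(compare_study(list(a = ctrl), "mean_length_um"), "two groups")
  expect_error(compare_study(list(a = ctrl, b = inf), "n_dislocations"),
               "should be one of")
  expect_error(compare_study(list(a = list(1), b = list(2)), "burden_percent",
                             method = "t_unpaired"), "n >= 2")
})
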