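# The flowchart engine is exercised with injected profiles so that every
# branch is reachable deterministically; the full selector is then run on a
# real decomposition for termination and trace consistency.

profile_table <- function(tbl) function(K) tbl[[as.character(K)]]

test_that("exactly one similar pair at the initial K stops immediately with K-1", {
  tbl <- list(`3` = c(0.30, 0.2005, 0.2000))       # one delta <= 0.001
  r <- VMDespeckle:::.k_search(profile_table(tbl), k_init = 3,
                               threshold = 0.001, k_min = 2, k_max = 12)
  expect_identical(r$final_K, 2L)
  expect_identical(vapply(r$tried, `[[`, "", "action"), "stop")
})

test_that("the search climbs while all modes are distinct and stops at one pair", {
  tbl <- list(`3` = c(0.30, 0.25, 0.20),
              `4` = c(0.30, 0.25, 0.20, 0.15),
              `5` = c(0.30, 0.25, 0.2005, 0.2000, 0.15))
  r <- VMDespeckle:::.k_search(profile_table(tbl), 3, 0.001, 2, 12)
  expect_identical(r$final_K, 4L)
  expect_identical(vapply(r$tried, `[[`, 0L, "k"), 3:5)
  expect_identical(vapply(r$tried, `[[`, "", "action"),
                   c("increase", "increase", "stop"))
})

test_that("several similar pairs drive K down to a single pair", {
  tbl <- list(`5` = c(0.30, 0.2005, 0.2001, 0.1502, 0.15),
              `4` = c(0.30, 0.2505, 0.2500, 0.20))
  r <- VMDespeckle:::.k_search(profile_table(tbl), 5, 0.001, 2, 12)
  expect_identical(r$final_K, 3L)
  expect_identical(vapply(r$tried, `[[`, "", "action"), c("decrease", "stop"))
})

test_that("the boundary condition delta == threshold counts as similar", {
  v <- c(0.30, 0.201, 0.200)
  thr <- v[2] - v[3]                               # delta exactly == threshold
  r <- VMDespeckle:::.k_search(profile_table(list(`3` = v)), 3, thr, 2, 12)
  expect_identical(r$final_K, 2L)
})

test_that("an increase/decrease oscillation trips the cycle guard", {
  tbl <- list(`3` = c(0.30, 0.25, 0.20),             # n = 0 -> increase
              `4` = c(0.30, 0.2005, 0.2001, 0.1999)) # n = 2 -> decrease
  r <- VMDespeckle:::.k_search(profile_table(tbl), 3, 0.001, 2, 12)
  expect_identical(r$final_K, 3L)                  # smallest K with a pair, minus 1
  expect_match(r$warning, "cycle")
})

test_that("reaching k_max with no similar pair ever seen is an error", {
  tbl <- setNames(lapply(3:6, function(K) seq(0.5, 0.1, length.out = K)),
                  as.character(3:6))
  expect_error(VMDespeckle:::.k_search(profile_table(tbl), 3, 0.001, 2, 6),
               "no similar-mode pair")
})

test_that("vif profiles are sorted, complete and deterministic", {
  g <- makeCompositePhantom(96, seed = 1) + noise_matrix(96, sd = 5, seed = 2)
  p <- vifProfile(g, 4, fast_vmd())
  expect_length(p, 4)
  expect_false(is.unsorted(rev(p)))
  expect_identical(p, vifProfile(g, 4, fast_vmd()))
  expect_error(vifProfile(g, 1, fast_vmd()), "K")
})

test_that("the full selector terminates and its trace replays the flowchart", {
  g <- makeCompositePhantom(128, seed = 1) +
    noise_matrix(128, sd = 6, seed = 3)
  r <- selectK(g, fast_vmd(), k_max = 8)
  expect_gte(r$final_K, 1L)
  expect_s4_class(r$trace, "KSelectTrace")
  # replay: every recorded action must follow from the recorded profile
  for (e in ksteps(r$trace)) {
    expect_length(e$delta, e$k - 1L)
    expect_equal(e$delta, -diff(e$vif), tolerance = 1e-12)
    n <- sum(e$delta <= r$trace@threshold)
    expect_identical(e$n, n)
    expected_action <- if (n == 0) "increase" else if (n > 1) "decrease" else "stop"
    expect_identical(e$action, expected_action)
  }
  # bounded number of profile evaluations (termination guarantee)
  expect_lte(length(ksteps(r$trace)), 8 - 2 + 3)
})
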