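toy_inventory <- function(values) {
  structure(data.frame(line = names(values), unit = "u",
                       value = unname(values)),
            class = c("inventory_table", "data.frame"))
}

test_that("characterization is the factor-weighted sum over lines", {
  inv <- toy_inventory(c(a = 2, b = -1, c = 4))

  # identity factors reproduce the inventory
  tab <- data.frame(category = c("X", "Y", "Z"), line = c("a", "b", "c"),
                    factor = 1)
  imp <- characterize(inv, tab)
  expect_equal(imp$impact, c(2, -1, 4))

  # zero inventory, zero impacts
  expect_true(all(characterize(toy_inventory(c(a = 0, b = 0, c = 0)),
                               tab)$impact == 0))

  # random factor matrix against an independent dot-product oracle
  set.seed(11)
  cats <- paste0("C", 1:4)
  lines <- paste0("L", 1:6)
  tab2 <- expand.grid(category = cats, line = lines,
                      stringsAsFactors = FALSE)
  tab2$factor <- rnorm(nrow(tab2))
  amounts <- rnorm(6)
  inv2 <- toy_inventory(stats::setNames(amounts, lines))
  imp2 <- characterize(inv2, tab2)
  fmat <- matrix(0, 4, 6, dimnames = list(cats, lines))
  fmat[cbind(tab2$category, tab2$line)] <- tab2$factor
  expect_equal(imp2$impact, unname(as.numeric(fmat %*% amounts)),
               tolerance = 1e-12)

  # linearity in the inventory
  inv_a <- toy_inventory(stats::setNames(rnorm(6), lines))
  inv_b <- toy_inventory(stats::setNames(rnorm(6), lines))
  inv_ab <- toy_inventory(stats::setNames(
    2 * inv_a$value + 3 * inv_b$value, lines))
  expect_equal(characterize(inv_ab, tab2)$impact,
               2 * characterize(inv_a, tab2)$impact +
                 3 * characterize(inv_b, tab2)$impact,
               tolerance = 1e-10)

  # unmatched lines are reported, not dropped silently
  expect_true("c" %in%
                attr(characterize(inv, tab[tab$line != "c", ]),
                     "uncharacterized"))
})

test_that("relative impact ratio matches its defining formula", {
  expect_equal(rir(1, 1), 0)
  expect_equal(rir(0, 0), 0)
  expect_equal(rir(1, 0), 1)
  expect_equal(rir(2, 1), 0.5)
  expect_equal(rir(1, 2), -0.5)

  # antisymmetry of the sign under argument swap
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1)
    expect_equal(sign(rir(a, b)), -sign(rir(b, a)))
  }

  # bounded for non-negative inputs
  for (i in 1:20) {
    v <- rir(runif(1, 0, 10), runif(1, 0, 10))
    expect_true(v >= -1 && v <= 1)
  }

  # net-avoided (negative) impacts may leave [-1, 1]: flagged, not clamped
  v <- rir(-3, 1)
  expect_true(isTRUE(attr(v, "out_of_range")))
})

test_that("heatmap classes switch exactly at +-0.5", {
  expect_equal(classify_rir(-0.6), "green")
  expect_equal(classify_rir(0), "yellow")
  expect_equal(classify_rir(0.51), "red")
  # boundaries belong to the comparable class
  expect_equal(classify_rir(c(-0.5, 0.5)), c("yellow", "yellow"))
  expect_equal(classify_rir(c(-0.5 - 1e-12, 0.5 + 1e-12)),
               c("green", "red"))
})

test_that("normalization ranks categories and selects a covering prefix", {
  imp <- structure(
    data.frame(category = c("GWP", "A", "B", "C", "D"),
               impact = c(1, 50, 30, 15, 4)),
    class = c("impact_result", "data.frame")
  )
  nf <- stats::setNames(rep(1, 5), c("GWP", "A", "B", "C", "D"))
  # toy PE vector (1, 50, 30, 15, 4): A+B+C = 95/100 reaches 95%
  sel <- normalize_and_select(imp, nf, coverage = 0.95)
  expect_setequal(sel$selected, c("A", "B", "C", "GWP"))

  # all-zero impacts: empty selection
  imp0 <- imp
  imp0$impact <- 0
  expect_length(normalize_and_select(imp0, nf)$selected, 0)

  # single nonzero category: that category (plus forced GWP)
  imp1 <- imp0
  imp1$impact[imp1$category == "B"] <- 7
  expect_setequal(normalize_and_select(imp1, nf)$selected, c("B", "GWP"))

  # missing factors are reported by name
  expect_error(normalize_and_select(imp, nf[-2]), "A")
  expect_error(normalize_and_select(imp, replace(nf, 1, 0)), "positive")
})

test_that("contribution shares are signed and normalized by magnitude", {
  inv <- toy_inventory(c(a = 2, b = -1))
  tab <- data.frame(category = rep("X", 2), line = c("a", "b"),
                    factor = 1, component = c("Resources", "Byproducts"))
  imp <- characterize(inv, tab)
  sh <- contribution_shares(imp)
  expect_equal(sh$Resources, 2 / 3)
  expect_equal(sh$Byproducts, -1 / 3)
})
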