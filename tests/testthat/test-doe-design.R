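test_that("composite designs carry the expected blocks and levels", {
  d <- generate_oacd(3, seed = 1)
  L <- design_levels(d)
  expect_true(all(L %in% 0:2))
  expect_true(all(L[d$block == "two_level", ] %in% c(0, 2)))
  expect_equal(sum(rowSums(L) == 0), 1)  # one vehicle/center run
  expect_setequal(unique(d$block), c("two_level", "three_level", "center"))
  # full 3^3 block: 27 three-level runs before dedup, each level 9x/column
  bal <- validate_design(d)$balance
  expect_true(all(bal$level0 == bal$level1 & bal$level1 == bal$level2))
  expect_error(generate_oacd(1), class = "tgmo_validation_error")
  expect_error(generate_oacd(14), class = "tgmo_validation_error")
})

test_that("the k=2 design contains the full 3^2 factorial", {
  d <- generate_oacd(2, seed = 9)
  L <- design_levels(d)
  combos <- unique(paste(L[, 1], L[, 2]))
  expect_length(combos, 9)
  expect_true(validate_design(d, "full_quadratic")$rank_ok)
})

test_that("full quadratic models are estimable for all supported sizes", {
  for (k in c(2, 4, 5, 7, 10, 13)) {
    v <- validate_design(generate_oacd(k, seed = 1), "full_quadratic")
    expect_true(v$rank_ok, label = paste("rank_ok at k =", k))
    expect_equal(v$p, 1 + 2 * k + k * (k - 1) / 2)
    expect_gt(v$d_efficiency, 0)
  }
})

test_that("three-level blocks are balanced orthogonal arrays", {
  # 18-run array: each level 6x per column
  d7 <- generate_oacd(7, seed = 1)
  bal <- validate_design(d7)$balance
  expect_true(all(bal$level0 == 6 & bal$level1 == 6 & bal$level2 == 6))
  # 27-run array: each level 9x per column, pairwise orthogonal after centering
  d10 <- generate_oacd(10, seed = 1)
  tri <- attr(d10, "three_level_block") - 1
  expect_true(all(abs(crossprod(tri) - diag(diag(crossprod(tri)))) < 1e-12))
})

test_that("designs are deterministic in (k, seed) and vary with seed", {
  a <- generate_oacd(5, seed = 11)
  b <- generate_oacd(5, seed = 11)
  c3 <- generate_oacd(5, seed = 12)
  expect_identical(a, b)
  expect_false(identical(design_levels(a), design_levels(c3)))
})

test_that("a constant drug column fails the rank check without erroring", {
  d <- generate_oacd(3, seed = 2)
  d$drug03 <- 0
  v <- validate_design(d, "full_quadratic")
  expect_false(v$rank_ok)
})

test_that("coded levels map onto half and full screening doses", {
  specs <- drug_specs(c("crizotinib", "telaglenastat", "U-104"),
                      cud_uM = c(0.664, 2.113, 9.524),
                      screen_dose_uM = c(0.664, 0.013, 9.524))
  d <- generate_oacd(3, drugs = specs$drug, seed = 3)
  conc <- map_to_concentrations(d, specs)
  L <- design_levels(d)
  expect_equal(conc$crizotinib[L[, "crizotinib"] == 2][1], 0.664)
  expect_true(all(conc$crizotinib[L[, "crizotinib"] == 0] == 0))
  expect_equal(conc$`U-104`[L[, "U-104"] == 1][1], 4.762)
  expect_error(map_to_concentrations(d, specs[-3, ]),
               class = "tgmo_validation_error")
})

test_that("design tables round-trip through CSV", {
  d <- generate_oacd(4, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, tmp)
  back <- readr::read_csv(tmp, show_col_types = FALSE)
  plain <- as.data.frame(d)
  attributes(plain)[c("drug_order", "k", "seed", "three_level_block")] <- NULL
  expect_equal(as.data.frame(back), plain)
})
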