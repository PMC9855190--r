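test_that("a planted main effect separates cleanly from null terms", {
  for (s in 1:20) {
    tab <- make_grid_table(seed = 900 + s, sd = 0.03, shift = c(dFC = 0.05))
    terms <- three_way_anova(tab)$full$terms
    planted_p <- terms$p[terms$term == "representation"]
    null_p <- terms$p[terms$term != "representation"]
    expect_lt(planted_p, 1e-10)
    # null terms may graze the 0.001 level by chance (120 tests across
    # seeds) but never approach the planted signal
    expect_gt(min(null_p), 1e-4)
  }
})

test_that("interaction pruning retains exactly the sub-alpha interactions", {
  tab <- make_grid_table(seed = 2, sd = 0.02, shift = c(dFC = 0.04))
  # plant a representation x atlas interaction
  tab$score <- tab$score +
    ifelse(tab$representation == "dFC" & tab$atlas == "AAL", 0.05, 0)
  av <- three_way_anova(tab, prune_alpha = 0.001)
  full <- av$full$terms
  inter <- full$term[grepl(":", full$term)]
  keep <- inter[full$p[match(inter, full$term)] <= 0.001]
  got <- av$pruned$terms$term
  expect_setequal(got, c("representation", "strategy", "atlas", keep))
  expect_true("representation:atlas" %in% got)
  expect_identical(av$full$ss_type, "III")
})

test_that("degenerate and deficient designs are flagged", {
  tab <- make_grid_table(seed = 1)
  tab$score <- 0.8
  res <- tryCatch(three_way_anova(tab), error = function(e) e)
  if (inherits(res, "error")) {
    succeed("zero-residual design rejected")
  } else {
    expect_true(all(res$full$terms$sum_sq < 1e-18))
  }
  expect_error(three_way_anova(make_grid_table(1)[, -1] |>
                                 transform(representation = "FC")),
               class = "dynconn_design_error")
})

test_that("single-factor reduction reproduces the classical one-way F", {
  for (s in 1:20) {
    tab <- make_grid_table(seed = 1200 + s, sd = 0.05,
                           shift = c(dFC = runif(1, 0, 0.05)))
    av <- three_way_anova(tab, factors = "representation")
    expect_equal(av$full$terms$F[av$full$terms$term == "representation"],
                 oneway_f_oracle(tab$score, tab$representation),
                 tolerance = 1e-8)
  }
})

test_that("type-III sums of squares are invariant to row and level order", {
  tab <- make_grid_table(seed = 77, shift = c(dFC = 0.05, AAL = 0.02))
  av <- three_way_anova(tab)
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  av2 <- three_way_anova(shuffled)
  expect_equal(av$full$terms$sum_sq, av2$full$terms$sum_sq, tolerance = 1e-10)

  relevel_tab <- tab
  relevel_tab$representation <- factor(tab$representation,
                                       levels = c("dFC", "FC"))
  av3 <- three_way_anova(relevel_tab)
  expect_equal(av$full$terms$sum_sq, av3$full$terms$sum_sq, tolerance = 1e-10)
})

test_that("balanced designs give matching type-I and type-III main effects", {
  tab <- make_grid_table(seed = 5, shift = c(dFC = 0.04))
  av <- three_way_anova(tab)
  dat <- tab
  for (f in c("representation", "strategy", "atlas")) dat[[f]] <- factor(dat[[f]])
  t1 <- anova(lm(score ~ representation * strategy * atlas, data = dat))
  for (f in c("representation", "strategy", "atlas")) {
    expect_equal(av$full$terms$sum_sq[av$full$terms$term == f],
                 t1[f, "Sum Sq"], tolerance = 1e-8, label = f)
  }
})

test_that("factor summaries report signed mean differences", {
  tab <- make_grid_table(seed = 3, sd = 0.001, shift = c(dFC = 0.05))
  s <- factor_effect_summary(tab, "representation")
  d <- s$differences
  dfc_minus_fc <- ifelse(d$level_a == "dFC", 1, -1) * d$difference
  expect_equal(dfc_minus_fc, 0.05, tolerance = 0.005)

  one <- factor_effect_summary(tab[tab$representation == "FC", ], "representation")
  expect_identical(nrow(one$means), 1L)
  expect_identical(nrow(one$differences), 0L)

  set.seed(4)
  shuf <- factor_effect_summary(tab[sample(nrow(tab)), ], "representation")
  expect_equal(shuf$means, s$means)
})

test_that("region frequency counts both endpoints with deterministic ranking", {
  out <- region_frequency(c("A__B_wk", "A__C_st"))
  expect_equal(out, data.frame(region = c("A", "B", "C"),
                               count = c(2L, 1L, 1L)))
  expect_identical(nrow(region_frequency(character(0))), 0L)

  sel <- c(sprintf("X__p%02d_wk", 1:24), "q__r_st")
  rf <- region_frequency(sel)
  expect_identical(rf$region[1], "X")
  expect_identical(rf$count[1], 24L)

  expect_error(region_frequency("not-a-pair"), "not-a-pair",
               class = "dynconn_parse_error")
})

test_that("weak/strong proportions partition the selected dynamic features", {
  p <- wk_st_proportions(c(sprintf("a__b%d_wk", 1:9), "a__c_st"))
  expect_equal(p, c(wk_fraction = 0.9, st_fraction = 0.1))
  expect_equal(wk_st_proportions(c("a__b_st", "c__d_st")),
               c(wk_fraction = 0, st_fraction = 1))
  expect_error(wk_st_proportions(c("a__b", "c__d")),
               class = "dynconn_value_error")
})
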