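test_that("regions partition into carrier groups A, B, C", {
  cn <- c(fa = 1L, mo = 2L, ch = 2L)
  nb <- matrix(integer(0), 3, 0, dimnames = list(c("fa", "mo", "ch"), NULL))
  expect_equal(assign_group(make_region(cn, nb, "fa", "mo", "ch")), "A")
  cn2 <- c(fa = 1L, mo = 1L, ch = 2L)
  expect_equal(assign_group(make_region(cn2, nb, "fa", "mo", "ch")), "B")
  cn3 <- c(fa = 2L, mo = 2L, ch = 1L)
  expect_equal(assign_group(make_region(cn3, nb, "fa", "mo", "ch")), "C")
  cn4 <- c(fa = 2L, mo = 2L, ch = 2L)
  expect_error(assign_group(make_region(cn4, nb, "fa", "mo", "ch")),
               "no CNV carrier")
})

test_that("transmission tally counts one event per child per region", {
  # duplication region, 5 children, transmitted to 2 of them
  cn <- c(fa = 3L, mo = 2L, c1 = 3L, c2 = 3L, c3 = 2L, c4 = 2L, c5 = 2L)
  # father haps A | BB; mother A | B
  nb <- matrix(c(2L,  # father ABB
                 1L,  # mother AB
                 2L, 3L,  # c1 dup + mother A -> ABB; c2 dup + mother B
                 0L, 0L, 1L), 7, 1,
               dimnames = list(names(cn), "m1"))
  nb["c1", 1] <- 2L; nb["c2", 1] <- 3L
  nb["c3", 1] <- 0L; nb["c4", 1] <- 0L; nb["c5", 1] <- 1L
  reg <- make_region(cn, nb, "fa", "mo", paste0("c", 1:5),
                     start = 1000L, end = 166245L)
  res <- phase_region(reg)
  expect_true(res$unambiguous)
  tt <- tally_transmissions(list(res))
  expect_equal(nrow(tt$records), 5L)
  expect_equal(sum(tt$records$transmitted_kind == "cnv"), 2L)
  expect_equal(sum(tt$records$transmitted_kind == "normal"), 3L)
  expect_equal(unique(tt$records$cnv_type), "duplication")
  all_row <- tt$table[tt$table$length_bin == "All", ]
  expect_equal(all_row$dup_cnv, 2L)
  expect_equal(all_row$dup_total, 5L)
  expect_equal(all_row$dup_rate, 0.4)

  # bin marginals sum to the All row
  bins <- tt$table[tt$table$length_bin != "All", ]
  expect_equal(sum(bins$all_total), all_row$all_total)
  expect_equal(bins$all_cnv, bins$del_cnv + bins$dup_cnv)
})

test_that("transmission tally rejects ambiguous or non-A input", {
  res_amb <- phase_region(denovo_ambiguous_trio_region())
  expect_error(tally_transmissions(list(res_amb)), "group C|ambiguous")
})

test_that("length bins are half-open with inclusive lower edges", {
  expect_equal(as.character(cnv_length_bin(c(9999, 10000, 29999, 30000,
                                             1e5 - 1, 1e5, 5e6))),
               c("<10kb", "10-30kb", "10-30kb", "30-100kb", "30-100kb",
                 ">100kb", ">100kb"))
})

test_that("the 50:50 transmission test reproduces known statistics", {
  expect_equal(round(transmission_bias_test(580, 671)$p_value, 3), 0.011)
  expect_equal(round(transmission_bias_test(70, 98)$p_value, 3), 0.037)
  expect_equal(transmission_bias_test(50, 50)$p_value, 1.0)
  # symmetry and range
  for (ab in list(c(3L, 9L), c(40L, 25L), c(1L, 1L))) {
    p1 <- transmission_bias_test(ab[1], ab[2])$p_value
    p2 <- transmission_bias_test(ab[2], ab[1])$p_value
    expect_equal(p1, p2)
    expect_gt(p1, 0)
    expect_lte(p1, 1)
  }
  expect_error(transmission_bias_test(0, 0), "zero total")
  # the uncorrected Pearson statistic is larger, its p smaller
  expect_lt(transmission_bias_test(580, 671, correct = FALSE)$p_value,
            transmission_bias_test(580, 671)$p_value)
})

test_that("multiple-testing adjustment is Bonferroni with a cap", {
  a <- multiple_testing_adjust(0.004, m = 10)
  expect_equal(a$adjusted, 0.04)
  expect_true(a$significant)
  b <- multiple_testing_adjust(0.02, m = 10)
  expect_equal(b$adjusted, 0.2)
  expect_false(b$significant)
  expect_equal(multiple_testing_adjust(0.9, m = 10)$adjusted, 1)
})

test_that("allelic variability flags within- and between-informativeness", {
  res <- phase_region(fig_dup_family_region())
  av <- allelic_variability(res$solutions[[1]])
  expect_equal(nrow(av), 1L)
  expect_equal(av$parent, "mother")
  expect_true(av$has_within)   # the AB tuple inside the gain haplotype
  expect_true(av$has_between)

  # gain haplotype AA everywhere vs normal hap with a B: between only
  sol <- list(father = list(cn = c(1L, 2L),
                            nb = matrix(c(1L, 0L), 2, 1, byrow = TRUE)),
              mother = list(cn = c(1L, 1L),
                            nb = matrix(0L, 2, 1)),
              schemes = list())
  av2 <- allelic_variability(sol)
  expect_true(av2$has_between)
  expect_false(av2$has_within)

  # monomorphic everywhere: neither
  sol$father$nb <- matrix(0L, 2, 1)
  av3 <- allelic_variability(sol)
  expect_false(av3$has_between)
  expect_false(av3$has_within)

  # a cn=1 haplotype can never be within-informative
  expect_true(all(av$cn[av$has_within] >= 2L))
})

test_that("type-I error of the bias test is calibrated at alpha = 0.05", {
  set.seed(42)
  k <- stats::rbinom(2000, 150, 0.5)
  rej <- vapply(k, function(x)
    transmission_bias_test(x, 150L - x)$p_value < 0.05, logical(1))
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("dataset summary reports efficiency and de novo annotations", {
  results <- list(phase_region(fig_dup_family_region()),
                  phase_region(denovo_ambiguous_trio_region()),
                  phase_region(denovo_intra_dup_trio_region()))
  s <- summarize_dataset(results)
  eff <- s$efficiency
  expect_equal(eff$pct[eff$group == "all"], round(100 * 2 / 3, 1))
  expect_equal(eff$pct[eff$group == "A"], 100)
  # only the unambiguous de novo duplication region contributes
  expect_equal(nrow(s$de_novo), 1L)
  expect_equal(s$de_novo$type, "duplication")
  expect_equal(s$de_novo$subtype, "DENOVO_DUP_INTRA")
  expect_equal(s$de_novo$parent_of_origin, "father")
  expect_equal(s$allelic$n_gain_haplotypes, 1L)
  expect_equal(s$allelic$pct_within, 100)
})
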