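test_that("parent phase enumeration partitions observed multisets", {
  # CN=2, markers AB, AA: the heterozygous marker forces the partition
  ph <- enumerate_parent_phases(nb = c(1L, 0L), cn = 2L)
  expect_length(ph, 1)
  expect_equal(ph[[1]]$cn, c(1L, 1L))
  expect_equal(sort(ph[[1]]$nb[, 1]), c(0L, 1L))
  expect_equal(ph[[1]]$nb[, 2], c(0L, 0L))

  # CN=0 degenerate: a single empty pair
  ph0 <- enumerate_parent_phases(nb = 0L, cn = 0L)
  expect_length(ph0, 1)
  expect_equal(ph0[[1]]$cn, c(0L, 0L))

  # CN=3 single marker AAB with split (1,2): {A}+{AB} and {B}+{AA}
  ph3 <- enumerate_parent_phases(nb = 1L, cn = 3L)
  expect_length(ph3, 2)
  keys <- sort(vapply(ph3, function(p)
    paste(p$cn[1], p$nb[1, 1], p$cn[2], p$nb[2, 1]), character(1)))
  expect_equal(keys, c("1 0 2 1", "1 1 2 0"))

  expect_error(enumerate_parent_phases(nb = 1L, cn = 5L), "unsupported")
})

test_that("phase enumeration respects configured cn splits", {
  ph <- enumerate_parent_phases(nb = 1L, cn = 3L,
                                config = phasing_config(
                                  cn_splits = list("3" = list(c(0, 3)))))
  expect_length(ph, 1)
  expect_equal(ph[[1]]$cn, c(0L, 3L))
  # CN=4 defaults: splits (1,3) and (2,2)
  ph4 <- enumerate_parent_phases(nb = 2L, cn = 4L)
  cns <- unique(t(vapply(ph4, `[[`, integer(2), "cn")))
  expect_equal(nrow(cns), 2L)
})

test_that("gamete enumeration covers Mendelian and de novo events", {
  phase <- list(cn = c(1L, 1L), nb = matrix(c(0L, 1L), 2, 1))  # A / B
  mend <- enumerate_gametes(phase, allow_nonmendelian = FALSE)
  expect_setequal(vapply(mend, `[[`, character(1), "event"),
                  "MENDELIAN")
  expect_length(mend, 2)

  full <- enumerate_gametes(phase, allow_nonmendelian = TRUE)
  evs <- vapply(full, `[[`, character(1), "event")
  # the empty deletion gamete exists once, sourced from either haplotype
  dels <- full[evs == "DENOVO_DELETION"]
  expect_length(dels, 1)
  expect_equal(dels[[1]]$cn, 0L)
  expect_equal(dels[[1]]$src, c(1L, 2L))
  # duplications: AA (intra from A), BB (intra from B), AB (inter, both)
  dups <- full[evs == "DENOVO_DUP"]
  dup_nb <- unname(sort(vapply(dups, function(g) g$nb, integer(1))))
  expect_equal(dup_nb, c(0L, 1L, 2L))
})

test_that("explaining a child prefers Mendelian pairings", {
  # father AB x mother AB -> child AA: unique double-A transmission
  pf <- list(cn = c(1L, 1L), nb = matrix(c(0L, 1L), 2, 1))
  res <- explain_child(2L, 0L, pf, pf)
  expect_equal(res$u, 0L)
  expect_equal(res$e, 0L)
  expect_length(res$pairings, 1)
  expect_equal(res$pairings[[1]]$father$event, "MENDELIAN")
  expect_equal(res$pairings[[1]]$father$nb, 0L)

  # deletion haplotype inherited from father: split (0,1) hap B,
  # child cn=1 genotype B at both markers
  pf <- list(cn = c(0L, 1L), nb = matrix(c(0L, 0L, 1L, 1L), 2, 2,
                                         byrow = TRUE))
  pm <- list(cn = c(1L, 1L), nb = matrix(c(0L, 0L, 1L, 1L), 2, 2,
                                         byrow = TRUE))
  res <- explain_child(1L, c(1L, 1L), pf, pm)
  expect_equal(res$u, 0L)
  expect_equal(res$e, 0L)
  # child received the paternal empty haplotype + maternal B: and the
  # paternal B + maternal empty is impossible (mother has no cn=0 hap)
  expect_length(res$pairings, 1)
  expect_equal(res$pairings[[1]]$father$cn, 0L)
  expect_equal(res$pairings[[1]]$mother$nb, c(1L, 1L))

  # de novo ambiguity: father AB, mother AB, child monoploid A
  pf <- list(cn = c(1L, 1L), nb = matrix(c(0L, 1L), 2, 1))
  res <- explain_child(1L, 0L, pf, pf)
  expect_equal(res$u, 0L)
  expect_equal(res$e, 1L)
  expect_length(res$pairings, 2)
  evs <- vapply(res$pairings, function(p)
    paste(p$father$event, p$mother$event), character(1))
  expect_setequal(evs, c("MENDELIAN DENOVO_DELETION",
                         "DENOVO_DELETION MENDELIAN"))
})

test_that("solution conservation holds on random simulated regions", {
  p <- sim_params_small()
  for (i in 1:25) {
    set.seed(300 + i)
    sim <- simulate_family_region(p, random_family(), i)
    reg <- select_region_markers(sim$region)
    res <- phase_region(reg)
    for (sol in res$solutions) {
      for (pp in c("father", "mother")) {
        pid <- if (pp == "father") reg$father_id else reg$mother_id
        expect_equal(as.integer(colSums(sol[[pp]]$nb)),
                     unname(reg$nb[pid, ]))
        expect_equal(sum(sol[[pp]]$cn), unname(reg$member_cn[pid]))
      }
      if (res$score[1] == 0L) {
        for (cid in names(sol$schemes)) {
          gsum <- sol$schemes[[cid]]$father$nb +
            sol$schemes[[cid]]$mother$nb
          expect_equal(as.integer(gsum), unname(reg$nb[cid, ]))
        }
      }
    }
  }
})

test_that("all-Mendelian optima exclude non-Mendelian events entirely", {
  p <- sim_params_small(event_rates = c(denovo_del = 0,
                                        denovo_dup_intra = 0,
                                        denovo_dup_inter = 0,
                                        upd_iso = 0, upd_hetero = 0))
  for (i in 1:20) {
    set.seed(600 + i)
    sim <- simulate_family_region(p, random_family(), i)
    reg <- select_region_markers(sim$region)
    res <- phase_region(reg)
    expect_equal(res$score, c(0L, 0L))
    for (sol in res$solutions) {
      evs <- unlist(lapply(sol$schemes, function(pair)
        c(pair$father$event, pair$mother$event)))
      expect_true(all(evs == "MENDELIAN"))
    }
  }
})

test_that("equivalence collapse is idempotent and merges relabelings", {
  reg <- fig_dup_family_region()
  res <- phase_region(reg)
  sols <- res$solutions
  # swap haplotypes of the father manually: collapses back to the same
  swapped <- sols[[1]]
  swapped$father$cn <- swapped$father$cn[2:1]
  swapped$father$nb <- swapped$father$nb[2:1, , drop = FALSE]
  merged <- collapse_equivalent_solutions(c(sols, list(swapped)))
  expect_length(merged, length(sols))
  again <- collapse_equivalent_solutions(merged)
  expect_equal(vapply(again, solution_key, character(1)),
               vapply(merged, solution_key, character(1)))
})

test_that("adding a consistent informative marker never adds solutions", {
  p <- sim_params_small(markers_range = 4L,
                        event_rates = c(denovo_del = 0,
                                        denovo_dup_intra = 0,
                                        denovo_dup_inter = 0,
                                        upd_iso = 0, upd_hetero = 0))
  for (i in 1:15) {
    set.seed(900 + i)
    sim <- simulate_family_region(p, random_family(), i)
    reg <- select_region_markers(sim$region)
    if (nrow(reg$markers) < 2L) next
    res_full <- phase_region(reg)
    drop_last <- function(r) {
      keep <- seq_len(nrow(r$markers) - 1L)
      r$markers <- r$markers[keep, , drop = FALSE]
      for (f in c("size", "nb", "conf", "nocall")) {
        r[[f]] <- r[[f]][, keep, drop = FALSE]
      }
      r
    }
    res_part <- phase_region(drop_last(reg))
    expect_lte(res_full$n_solutions, res_part$n_solutions)
  }
})

test_that("search budget violations raise an informative error", {
  cfg <- phasing_config(max_combinations = 1)
  reg <- fig_dup_family_region()
  expect_error(phase_region(reg, config = cfg), "budget")
})

test_that("degenerate regions with no markers phase through copy numbers", {
  cn <- c(fa = 1L, mo = 2L, ch = 1L)
  nb <- matrix(integer(0), 3, 0, dimnames = list(c("fa", "mo", "ch"), NULL))
  reg <- make_region(cn, nb, "fa", "mo", "ch")
  res <- phase_region(reg)
  expect_equal(res$score, c(0L, 0L))
  expect_true(res$unambiguous)  # deletion transmission forced by CN
  sol <- res$solutions[[1]]
  expect_equal(sol$schemes$ch$father$cn, 0L)
})
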