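test_that("simulation is deterministic given the seed", {
  p <- sim_params(n_families = 4)
  d1 <- simulate_dataset(p, seed = 7)
  d2 <- simulate_dataset(p, seed = 7)
  expect_identical(d1, d2)
  # per-family sub-seeding: family i does not depend on families before it
  p1 <- sim_params(n_families = 2)
  d3 <- simulate_dataset(p1, seed = 7)
  expect_identical(d1$sims[[2]]$region$nb, d3$sims[[2]]$region$nb)
})

test_that("zero event rates give purely Mendelian children", {
  p <- sim_params(n_families = 1,
                  event_rates = c(denovo_del = 0, denovo_dup_intra = 0,
                                  denovo_dup_inter = 0, upd_iso = 0,
                                  upd_hetero = 0))
  set.seed(2)
  for (i in 1:10) {
    sim <- simulate_family_region(p, random_family(3), i)
    evs <- unlist(lapply(sim$truth$schemes, function(pair)
      c(pair$father$event, pair$mother$event)))
    expect_true(all(evs == "MENDELIAN"))
  }
})

test_that("forced de novo deletions reduce the gamete copy number", {
  p <- sim_params(n_families = 1,
                  carrier_config = c(A_del = 0, A_dup2 = 1, A_dup3 = 0,
                                     B_del = 0, none = 0),
                  event_rates = c(denovo_del = 1, denovo_dup_intra = 0,
                                  denovo_dup_inter = 0, upd_iso = 0,
                                  upd_hetero = 0))
  set.seed(3)
  fam <- list(family_id = "F", father_id = "fa", mother_id = "mo",
              child_ids = "c1")
  sim <- simulate_family_region(p, fam, 1)
  pair <- sim$truth$schemes$c1
  del <- if (pair$father$event == "DENOVO_DELETION") pair$father else
    pair$mother
  expect_equal(del$event, "DENOVO_DELETION")
  parent <- if (pair$father$event == "DENOVO_DELETION") sim$truth$father
  else sim$truth$mother
  expect_equal(del$cn, parent$cn[del$src] - 1L)
})

test_that("observed genotypes are the multiset unions of truth haplotypes", {
  p <- sim_params_small()
  for (i in 1:10) {
    set.seed(40 + i)
    sim <- simulate_family_region(p, random_family(3), i)
    r <- sim$region
    expect_equal(unname(r$nb[r$father_id, ]),
                 as.integer(colSums(sim$truth$father$nb)))
    expect_equal(unname(r$nb[r$mother_id, ]),
                 as.integer(colSums(sim$truth$mother$nb)))
    for (cid in r$child_ids) {
      pair <- sim$truth$schemes[[cid]]
      expect_equal(unname(r$nb[cid, ]),
                   as.integer(pair$father$nb + pair$mother$nb))
      expect_equal(unname(r$member_cn[cid]),
                   pair$father$cn + pair$mother$cn)
    }
  }
})

test_that("noise injection honours its rates and leaves truth untouched", {
  p0 <- sim_params(n_families = 1)
  set.seed(5)
  sim <- simulate_family_region(p0, random_family(), 1)
  same <- inject_noise(sim, p0)  # all rates zero: identity
  expect_identical(same, sim)

  p1 <- sim_params(n_families = 1, nocall_rate = 1)
  noisy <- inject_noise(sim, p1)
  expect_true(all(noisy$region$nocall))
  expect_identical(noisy$truth, sim$truth)
  reg <- select_region_markers(noisy$region)
  expect_equal(nrow(reg$markers), 0L)
  expect_equal(reg$flag, "uninformative")
})

test_that("written datasets round-trip through the parsers", {
  p <- sim_params(n_families = 5, nocall_rate = 0.02)
  d <- simulate_dataset(p, seed = 11)
  dir <- withr::local_tempdir()
  paths <- write_dataset(d, dir)
  expect_true(all(file.exists(paths)))

  genos <- read_genotype_table(paths[["genotypes"]])
  for (sim in d$sims) {
    r <- sim$region
    for (s in rownames(r$nb)) {
      g <- genos[genos$sample_id == s &
                   genos$marker_id %in% r$markers$marker_id, ]
      g <- g[match(r$markers$marker_id, g$marker_id), ]
      expect_equal(g$no_call, unname(r$nocall[s, ]))
      obs <- ifelse(r$nocall[s, ], NA_integer_, r$nb[s, ])
      expect_equal(g$nb, unname(obs))
    }
  }
  calls_a <- read_cnv_calls(paths[["calls_a"]])
  calls_b <- read_cnv_calls(paths[["calls_b"]])
  expect_equal(nrow(calls_a), nrow(calls_b))
  fams <- read_pedigree(paths[["pedigree"]])
  expect_length(fams, 5)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_length(truth, 5)
  expect_true(all(vapply(truth, function(x)
    is.character(x$solution_key), logical(1))))
})

test_that("unambiguous fraction grows with marker count", {
  frac_unamb <- function(n_markers, seeds) {
    p <- sim_params(n_families = 1, markers_range = n_markers)
    mean(vapply(seeds, function(s) {
      set.seed(s)
      sim <- simulate_family_region(p, random_family(), s)
      phase_region(select_region_markers(sim$region))$unambiguous
    }, logical(1)))
  }
  seeds <- 1:40
  expect_gte(frac_unamb(6L, seeds), frac_unamb(1L, seeds))
})
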