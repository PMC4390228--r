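fam1 <- list(family_id = "T1", father_id = "fa", mother_id = "mo",
             child_ids = c("c1", "c2"))

geno_table <- function(markers, members, nb_by_member, cn_by_member,
                       chrom = "1", conf = 0.95) {
  do.call(rbind, lapply(members, function(s) {
    data.frame(sample_id = s, marker_id = names(markers), chrom = chrom,
               pos = unname(markers),
               genotype = format_genotype(rep(cn_by_member[[s]],
                                              length(markers)),
                                          nb_by_member[[s]]),
               size = rep(cn_by_member[[s]], length(markers)),
               nb = nb_by_member[[s]], no_call = FALSE,
               confidence = conf)
  }))
}

base_call <- function(sample, cn = 1L, start = 1000L, end = 9000L,
                      caller = "qs", chrom = "1") {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             cn = cn, lbf = 30, caller = caller, n_markers = 5L,
             length = end - start + 1L)
}

mk_genos <- function() {
  markers <- c(rs1 = 2000L, rs2 = 4000L, rs3 = 6000L)
  geno_table(markers, c("fa", "mo", "c1", "c2"),
             list(fa = c(0L, 1L, 0L), mo = c(1L, 1L, 1L),
                  c1 = c(1L, 2L, 1L), c2 = c(0L, 1L, 0L)),
             list(fa = 1L, mo = 2L, c1 = 2L, c2 = 1L))
}

test_that("a single-carrier call converges into a group-A region", {
  genos <- mk_genos()
  calls <- rbind(base_call("fa"), base_call("c2"))
  regs <- converge_family_regions(calls, calls[0, ], list(fam1), genos)
  expect_length(regs, 1)
  r <- regs[[1]]
  expect_equal(r$carrier_parents, "father")
  expect_equal(unname(r$member_cn[c("fa", "mo", "c1", "c2")]),
               c(1L, 2L, 2L, 1L))
  expect_equal(nrow(r$markers), 3L)
  expect_equal(assign_group(r), "A")
})

test_that("a raw single-caller call in any member excludes the region", {
  genos <- mk_genos()
  calls <- base_call("fa")
  raw <- base_call("c1", cn = 1L, start = 3000L, end = 5000L,
                   caller = "pennOnly")
  expect_message(
    regs <- converge_family_regions(calls, raw, list(fam1), genos),
    "single-caller")
  expect_length(regs, 0)
  # non-overlapping raw call elsewhere does not exclude
  raw2 <- base_call("c1", start = 50000L, end = 60000L)
  regs <- converge_family_regions(calls, raw2, list(fam1), genos)
  expect_length(regs, 1)
})

test_that("intersected multi-carrier regions require 3 shared markers", {
  genos <- mk_genos()
  # father and c2 calls overlap but their intersection holds 2 markers
  calls <- rbind(base_call("fa", start = 1000L, end = 4500L),
                 base_call("c2", start = 3500L, end = 9000L))
  expect_message(
    regs <- converge_family_regions(calls, calls[0, ], list(fam1), genos),
    "fewer than 3 shared markers")
  expect_length(regs, 0)
  # a single carrier is exempt from the shared-marker rule
  calls1 <- base_call("fa", start = 1000L, end = 2500L)  # 1 marker
  regs <- converge_family_regions(calls1, calls1[0, ], list(fam1), genos)
  expect_length(regs, 1)
})

test_that("overlapping same-member calls with different cn are complex", {
  genos <- mk_genos()
  calls <- rbind(base_call("fa", cn = 1L),
                 base_call("fa", cn = 0L, start = 4000L, end = 9500L))
  expect_message(
    regs <- converge_family_regions(calls, calls[0, ], list(fam1), genos),
    "complex")
  expect_length(regs, 0)
})

test_that("identical dual-caller call sets lose no region", {
  genos <- mk_genos()
  a <- rbind(base_call("fa"), base_call("c2"))
  b <- a; b$caller <- "pc"
  confirmed <- intersect_caller_calls(a, b)
  raw <- single_caller_raw_calls(a, b)
  expect_equal(nrow(raw), 0L)
  regs <- converge_family_regions(confirmed, raw, list(fam1), genos)
  expect_length(regs, 1)
})

test_that("marker selection drops NC, low-confidence and monomorphic", {
  # marker layout mirrors the worked filtering example: one NC marker,
  # one monomorphic marker, informative markers kept
  cn <- c(fa = 2L, mo = 3L, ch = 2L)
  nb <- matrix(c(1L, 0L, 1L, 1L,
                 1L, 0L, 2L, 1L,
                 1L, 0L, 1L, 0L), 3, 4, byrow = TRUE,
               dimnames = list(c("fa", "mo", "ch"),
                               c("rs_a", "rs_mono", "rs_nc", "rs_b")))
  nocall <- matrix(FALSE, 3, 4, dimnames = dimnames(nb))
  nocall["ch", "rs_nc"] <- TRUE
  reg <- make_region(cn, nb, "fa", "mo", "ch", nocall = nocall,
                     selected = FALSE)
  out <- select_region_markers(reg)
  expect_equal(out$markers$marker_id, c("rs_a", "rs_b"))

  # a single low-confidence member kills the marker family-wide
  conf <- matrix(0.99, 3, 4, dimnames = dimnames(nb))
  conf["mo", "rs_a"] <- 0.94
  reg <- make_region(cn, nb, "fa", "mo", "ch", conf = conf,
                     selected = FALSE)
  out <- select_region_markers(reg)
  expect_false("rs_a" %in% out$markers$marker_id)
})

test_that("regions with no surviving markers are flagged uninformative", {
  cn <- c(fa = 2L, mo = 2L, ch = 2L)
  nb <- matrix(0L, 3, 2, dimnames = list(c("fa", "mo", "ch"),
                                         c("m1", "m2")))  # all AA
  reg <- make_region(cn, nb, "fa", "mo", "ch", selected = FALSE)
  out <- select_region_markers(reg)
  expect_equal(nrow(out$markers), 0L)
  expect_equal(out$flag, "uninformative")
})
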