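# Seeded simulator of nuclear-family CNV regions with known truth.
#
# The generator draws parental haplotypes (haploid copy numbers per the
# carrier configuration, allele content i.i.d. Bernoulli per copy), forms
# each child's gametes by Mendelian transmission or one non-Mendelian
# event, and emits the observed multiploid genotypes, CNV calls from two
# concordant pseudo-callers, the pedigree, and the ground-truth family
# solution.  Simulated non-Mendelian events are constrained to be
# observable: a child whose genotypes are also explainable by purely
# Mendelian transmission of some parental haplotype partition is redrawn,
# so the recorded truth is always among the parsimony-optimal solutions.

#' Simulation parameters
#'
#' Defaults emulate a family SNP-array CNV dataset: predominantly
#' single-carrier (group A) deletion regions with a smaller share of
#' duplication carriers and double-carrier (group B) regions, trios plus
#' a tail of larger sibships, and rare non-Mendelian events.
#'
#' @param n_families Number of families (one CNV region each).
#' @param children_dist Named probabilities for the number of children.
#' @param markers_range Integer vector of possible marker counts per
#'   region.
#' @param allele_freq B-allele frequency in (0,1), shared by all copies.
#' @param carrier_config Named weights over carrier configurations:
#'   `A_del` (one parent 0/1), `A_dup2` (one parent 1/2), `A_dup3` (one
#'   parent 1/3), `B_del` (both parents 0/1), `none` (all normal).
#' @param event_rates Named per-child probabilities of the non-Mendelian
#'   events `denovo_del`, `denovo_dup_intra`, `denovo_dup_inter`,
#'   `upd_iso`, `upd_hetero`; at most one event is drawn per child, with
#'   the remainder Mendelian.
#' @param nocall_rate,lowconf_rate,genotype_error_rate Per-cell noise
#'   probabilities: no-call, confidence below threshold, single-allele
#'   flip.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_families = 40,
                       children_dist = c("1" = 0.60, "2" = 0.20, "3" = 0.12,
                                         "4" = 0.05, "5" = 0.03),
                       markers_range = 3:8,
                       allele_freq = 0.4,
                       carrier_config = c(A_del = 0.70, A_dup2 = 0.13,
                                          A_dup3 = 0.05, B_del = 0.045,
                                          none = 0.075),
                       event_rates = c(denovo_del = 0.02,
                                       denovo_dup_intra = 0.01,
                                       denovo_dup_inter = 0.01,
                                       upd_iso = 0.005,
                                       upd_hetero = 0.005),
                       nocall_rate = 0, lowconf_rate = 0,
                       genotype_error_rate = 0) {
  stopifnot(allele_freq > 0, allele_freq < 1,
            all(event_rates >= 0), sum(event_rates) <= 1,
            all(carrier_config >= 0), sum(carrier_config) > 0,
            nocall_rate >= 0, nocall_rate <= 1,
            lowconf_rate >= 0, lowconf_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1)
  need_ev <- c("denovo_del", "denovo_dup_intra", "denovo_dup_inter",
               "upd_iso", "upd_hetero")
  stopifnot(all(need_ev %in% names(event_rates)))
  structure(list(n_families = n_families,
                 children_dist = children_dist / sum(children_dist),
                 markers_range = as.integer(markers_range),
                 allele_freq = allele_freq,
                 carrier_config = carrier_config / sum(carrier_config),
                 event_rates = event_rates[need_ev],
                 nocall_rate = nocall_rate, lowconf_rate = lowconf_rate,
                 genotype_error_rate = genotype_error_rate),
            class = "sim_params")
}

.sample1 <- function(x) x[sample.int(length(x), 1L)]

# Mendelian explainability of one child's genotypes given the parents'
# observed genotypes: because the haplotype partition is free per marker,
# a child is Mendelian-explainable iff some allowed (father part, mother
# part) copy-number pair sums to the child CN and at every marker the
# child's B count splits into feasible per-parent contributions.
.mendelian_explainable <- function(child_cn, child_nb, f_cn, f_nb,
                                   m_cn, m_nb, config = phasing_config()) {
  f_parts <- unique(unlist(cn_splits_for(f_cn, config)))
  m_parts <- unique(unlist(cn_splits_for(m_cn, config)))
  for (cf in f_parts) {
    cm <- child_cn - cf
    if (!(cm %in% m_parts)) next
    ok <- TRUE
    for (j in seq_along(child_nb)) {
      fb <- .sub_nb_range(cf, f_cn, f_nb[j])
      mb <- .sub_nb_range(cm, m_cn, m_nb[j])
      if (!any((child_nb[j] - fb) %in% mb)) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Simulate one family CNV region with known truth
#'
#' Draws are taken from the current RNG state; seed upstream for
#' reproducibility (see [simulate_dataset()]).
#'
#' @param params A [sim_params()] object.
#' @param family A family list (`family_id`, `father_id`, `mother_id`,
#'   `child_ids`).
#' @param region_index Integer used to form region/marker identifiers.
#' @return A list with `region` (a `cnv_region`), `truth` (the generating
#'   family solution), `calls` (two concordant pseudo-caller call sets),
#'   `carrier_type`, and `has_carrier`.
#' @export
simulate_family_region <- function(params, family, region_index = 1L) {
  m <- .sample1(params$markers_range)
  chrom <- as.character(.sample1(1:22))
  len <- as.integer(round(exp(stats::runif(1, log(2e3), log(5e5)))))
  start <- 1000000L + sample.int(199000000L, 1L)
  end <- start + len - 1L
  pos <- start + sort(sample.int(len, m)) - 1L
  ctype <- .sample1_w(names(params$carrier_config), params$carrier_config)
  hap_cns <- switch(ctype,
                    A_del = list(c(0L, 1L), c(1L, 1L)),
                    A_dup2 = list(c(1L, 2L), c(1L, 1L)),
                    A_dup3 = list(c(1L, 3L), c(1L, 1L)),
                    B_del = list(c(0L, 1L), c(0L, 1L)),
                    none = list(c(1L, 1L), c(1L, 1L)))
  if (startsWith(ctype, "A_") && stats::runif(1) < 0.5) {
    hap_cns <- rev(hap_cns)
  }
  draw_phase <- function(cns) {
    list(cn = cns,
         nb = matrix(c(stats::rbinom(m, cns[1], params$allele_freq),
                       stats::rbinom(m, cns[2], params$allele_freq)),
                     nrow = 2L, byrow = TRUE))
  }
  fph <- draw_phase(hap_cns[[1]])
  mph <- draw_phase(hap_cns[[2]])
  f_gt <- as.integer(colSums(fph$nb)); f_cn <- sum(fph$cn)
  m_gt <- as.integer(colSums(mph$nb)); m_cn <- sum(mph$cn)

  draw_gamete <- function(phase, kind) {
    # returns scheme or NULL when the draw is infeasible
    if (kind == "mend") {
      i <- .sample1(1:2)
      return(.scheme("MENDELIAN", phase$cn[i], phase$nb[i, ], i))
    }
    if (kind == "denovo_del") {
      cand <- which(phase$cn >= 1L)
      if (!length(cand)) return(NULL)
      i <- .sample1(cand)
      tgt <- phase$cn[i] - 1L
      nb <- vapply(seq_len(m), function(j)
        .sample1(.sub_nb_range(tgt, phase$cn[i], phase$nb[i, j])),
        integer(1))
      return(.scheme("DENOVO_DELETION", tgt, nb, i))
    }
    # duplications
    cand <- which(phase$cn >= 1L & phase$cn + 1L <= 3L)
    if (kind == "denovo_dup_inter") cand <- cand[phase$cn[3L - cand] >= 1L]
    if (!length(cand)) return(NULL)
    i <- .sample1(cand)
    src_mode <- if (kind == "denovo_dup_intra") i else 3L - i
    mh_cn <- phase$cn[src_mode]; mh_nb <- phase$nb[src_mode, ]
    extra <- vapply(seq_len(m), function(j) {
      opts <- c(if ((mh_cn - mh_nb[j]) >= 1L) 0L, if (mh_nb[j] >= 1L) 1L)
      .sample1(opts)
    }, integer(1))
    .scheme("DENOVO_DUP", phase$cn[i] + 1L, phase$nb[i, ] + extra, i)
  }

  kids <- family$child_ids
  schemes <- stats::setNames(vector("list", length(kids)), kids)
  child_cn <- stats::setNames(integer(length(kids)), kids)
  child_nb <- matrix(0L, nrow = length(kids), ncol = m,
                     dimnames = list(kids, NULL))
  ev <- params$event_rates
  p_upd <- ev[["upd_iso"]] + ev[["upd_hetero"]]
  p_meio <- ev[c("denovo_del", "denovo_dup_intra", "denovo_dup_inter")]
  for (cid in kids) {
    ok <- FALSE
    for (attempt in 1:100) {
      u <- stats::runif(1)
      pair <- NULL
      if (u < p_upd) {
        kind <- if (stats::runif(1) * p_upd < ev[["upd_iso"]])
          "UPD_ISO" else "UPD_HETERO"
        parent <- .sample1(c("father", "mother"))
        ph <- if (parent == "father") fph else mph
        if (kind == "UPD_ISO") {
          i <- .sample1(1:2)
          if (2L * ph$cn[i] > 4L) next
          carrier <- .scheme("UPD_ISO", 2L * ph$cn[i], 2L * ph$nb[i, ], i)
        } else {
          carrier <- .scheme("UPD_HETERO", sum(ph$cn),
                             as.integer(colSums(ph$nb)), c(1L, 2L))
        }
        absent <- .scheme("ABSENT", 0L, rep(0L, m), integer(0))
        pair <- if (parent == "father")
          list(father = carrier, mother = absent)
        else list(father = absent, mother = carrier)
      } else {
        # at most one de novo event per child, on a random parent
        u2 <- u - p_upd
        kind <- "mend"
        for (k in names(p_meio)) {
          if (u2 < p_meio[[k]]) { kind <- k; break }
          u2 <- u2 - p_meio[[k]]
        }
        ev_parent <- .sample1(c("father", "mother"))
        gf <- draw_gamete(fph, if (ev_parent == "father") kind else "mend")
        gm <- draw_gamete(mph, if (ev_parent == "mother") kind else "mend")
        if (is.null(gf) || is.null(gm)) next
        pair <- list(father = gf, mother = gm)
      }
      ccn <- pair$father$cn + pair$mother$cn
      if (ccn > 4L) next
      cnb <- pair$father$nb + pair$mother$nb
      nonmend <- pair$father$event != "MENDELIAN" ||
        pair$mother$event != "MENDELIAN"
      if (nonmend &&
          .mendelian_explainable(ccn, cnb, f_cn, f_gt, m_cn, m_gt)) {
        next  # event not observable; redraw
      }
      schemes[[cid]] <- pair
      child_cn[cid] <- ccn
      child_nb[cid, ] <- cnb
      ok <- TRUE
      break
    }
    if (!ok) stop("simulate_family_region: no feasible draw for child ",
                  cid, " after 100 attempts")
  }

  members <- c(family$father_id, family$mother_id, kids)
  member_cn <- stats::setNames(c(f_cn, m_cn, child_cn[kids]), members)
  nbm <- rbind(f_gt, m_gt, child_nb)
  rownames(nbm) <- members
  sizem <- matrix(member_cn, nrow = length(members), ncol = m,
                  dimnames = list(members, NULL))
  storage.mode(nbm) <- "integer"
  storage.mode(sizem) <- "integer"
  mk <- data.frame(marker_id = sprintf("mk%04d_%02d", region_index,
                                       seq_len(m)),
                   pos = pos)
  dimnames(nbm) <- list(members, mk$marker_id)
  dimnames(sizem) <- list(members, mk$marker_id)
  confm <- matrix(0.99, nrow = length(members), ncol = m,
                  dimnames = dimnames(nbm))
  nocallm <- matrix(FALSE, nrow = length(members), ncol = m,
                    dimnames = dimnames(nbm))
  carrier_parents <- c("father", "mother")[
    c(f_cn != 2L, m_cn != 2L)]
  region <- structure(list(
    region_id = paste0(family$family_id, "_", chrom, "_", start),
    family_id = family$family_id, chrom = chrom, start = start, end = end,
    father_id = family$father_id, mother_id = family$mother_id,
    child_ids = kids, member_cn = member_cn,
    carrier_parents = carrier_parents,
    markers = mk, size = sizem, nb = nbm, conf = confm, nocall = nocallm,
    selected = FALSE, flag = ""
  ), class = "cnv_region")
  truth <- list(father = fph, mother = mph, schemes = schemes)
  carriers <- members[member_cn != 2L]
  calls <- if (length(carriers)) {
    do.call(rbind, lapply(carriers, function(s) {
      data.frame(sample_id = s, chrom = chrom, start = start, end = end,
                 cn = member_cn[[s]], lbf = 30,
                 caller = c("callerA", "callerB"), n_markers = m,
                 length = end - start + 1L)
    }))
  } else {
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(), cn = integer(),
               lbf = numeric(), caller = character(),
               n_markers = integer(), length = integer())
  }
  list(region = region, truth = truth, calls = calls,
       carrier_type = ctype, has_carrier = length(carriers) > 0L,
       family = family)
}

#' Restrict a family solution to a subset of markers
#'
#' Subsets every haplotype and gamete of the solution to the given marker
#' columns.  Used to compare a simulated ground truth against results on
#' a region whose marker set was reduced by [select_region_markers()].
#'
#' @param sol A family solution.
#' @param idx Integer or logical index of markers to keep (in the
#'   solution's original marker order).
#' @return The solution restricted to those markers.
#' @export
subset_solution_markers <- function(sol, idx) {
  for (p in c("father", "mother")) {
    sol[[p]]$nb <- sol[[p]]$nb[, idx, drop = FALSE]
  }
  for (cid in names(sol$schemes)) {
    for (p in c("father", "mother")) {
      sol$schemes[[cid]][[p]]$nb <- sol$schemes[[cid]][[p]]$nb[idx]
    }
  }
  sol
}

#' Ground truth of a simulated region, aligned to a processed region
#'
#' @param sim Output of [simulate_family_region()].
#' @param region The (possibly marker-filtered) `cnv_region` being
#'   phased; defaults to the simulation's own region.
#' @return The truth solution restricted to the region's markers.
#' @export
truth_solution <- function(sim, region = sim$region) {
  idx <- match(region$markers$marker_id, sim$region$markers$marker_id)
  subset_solution_markers(sim$truth, idx)
}

.sample1_n <- function(x, n) x[sample.int(length(x), n)]
.sample1_w <- function(x, w) x[sample.int(length(x), 1L, prob = w)]

#' Inject genotype-level noise into a simulated region
#'
#' Marks random member-by-marker cells as no-calls, lowers their call
#' confidence below the selection threshold, or flips one allele of the
#' observed multiset (size-preserving).  The recorded truth is untouched.
#'
#' @param sim Output of [simulate_family_region()].
#' @param params A [sim_params()] with the noise rates to apply.
#' @return The modified simulation object.
#' @export
inject_noise <- function(sim, params) {
  r <- sim$region
  n <- length(r$member_cn); m <- nrow(r$markers)
  if (m == 0L || n == 0L) return(sim)
  nc <- matrix(stats::runif(n * m) < params$nocall_rate, n, m)
  lc <- matrix(stats::runif(n * m) < params$lowconf_rate, n, m)
  fl <- matrix(stats::runif(n * m) < params$genotype_error_rate, n, m)
  r$nocall <- r$nocall | nc
  r$conf[lc] <- 0.90
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (!fl[i, j] || r$size[i, j] == 0L) next
      nb <- r$nb[i, j]
      dirs <- c(if (nb < r$size[i, j]) 1L, if (nb > 0L) -1L)
      r$nb[i, j] <- nb + .sample1(dirs)
    }
  }
  sim$region <- r
  sim
}

#' Simulate a full family dataset
#'
#' One CNV region per family.  A single root seed drives everything;
#' per-family sub-seeds are derived by counter so that family `i` is
#' reproducible independently of how many families precede it.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer root seed.
#' @return A list of class `cnv_simulation`: `sims` (per-family
#'   simulations, noise applied), `families`, `params`, `seed`.
#' @export
simulate_dataset <- function(params = sim_params(), seed = 1L) {
  sims <- vector("list", params$n_families)
  fams <- vector("list", params$n_families)
  for (i in seq_len(params$n_families)) {
    set.seed((as.integer(seed) + 104729L * i) %% 2147483647L)
    nk <- as.integer(.sample1_w(names(params$children_dist),
                                params$children_dist))
    fid <- sprintf("F%03d", i)
    family <- list(family_id = fid,
                   father_id = paste0(fid, "_fa"),
                   mother_id = paste0(fid, "_mo"),
                   child_ids = paste0(fid, "_c", seq_len(nk)))
    sim <- simulate_family_region(params, family, i)
    sims[[i]] <- inject_noise(sim, params)
    fams[[i]] <- family
  }
  names(fams) <- vapply(fams, `[[`, character(1), "family_id")
  structure(list(params = params, seed = seed, sims = sims,
                 families = fams),
            class = "cnv_simulation")
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Emits `genotypes.tsv`, `calls_a.tsv` and `calls_b.tsv` (two concordant
#' pseudo-callers, so convergence keeps every region), `pedigree.ped` and
#' `truth.json`.
#'
#' @param simulation A `cnv_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(simulation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             calls_a = file.path(dir, "calls_a.tsv"),
             calls_b = file.path(dir, "calls_b.tsv"),
             pedigree = file.path(dir, "pedigree.ped"),
             truth = file.path(dir, "truth.json"))
  grows <- list(); arows <- list(); brows <- list(); prows <- list()
  truth <- list()
  for (sim in simulation$sims) {
    r <- sim$region
    members <- rownames(r$size)
    for (s in members) {
      if (nrow(r$markers)) {
        gt <- ifelse(r$nocall[s, ], "NC",
                     format_genotype(r$size[s, ], r$nb[s, ]))
        grows[[length(grows) + 1L]] <- data.frame(
          sample_id = s, marker_id = r$markers$marker_id, chrom = r$chrom,
          pos = r$markers$pos, genotype = gt,
          confidence = r$conf[s, ])
      }
    }
    if (nrow(sim$calls)) {
      a <- sim$calls[sim$calls$caller == "callerA", ]
      b <- sim$calls[sim$calls$caller == "callerB", ]
      arows[[length(arows) + 1L]] <- a[, setdiff(names(a), "length")]
      brows[[length(brows) + 1L]] <- b[, setdiff(names(b), "length")]
    }
    fam <- sim$family
    prows[[length(prows) + 1L]] <- data.frame(
      family_id = fam$family_id,
      individual_id = c(fam$father_id, fam$mother_id, fam$child_ids),
      father_id = c("0", "0", rep(fam$father_id, length(fam$child_ids))),
      mother_id = c("0", "0", rep(fam$mother_id, length(fam$child_ids))),
      sex = c("1", "2", rep("0", length(fam$child_ids))),
      phenotype = "0")
    truth[[r$region_id]] <- list(
      family_id = fam$family_id,
      member_cn = as.list(r$member_cn),
      carrier_type = sim$carrier_type,
      solution_key = solution_key(sim$truth))
  }
  hdr_g <- data.frame(sample_id = character(), marker_id = character(),
                      chrom = character(), pos = integer(),
                      genotype = character(), confidence = numeric())
  hdr_c <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(), cn = integer(),
                      lbf = numeric(), caller = character(),
                      n_markers = integer())
  wt <- function(rows, hdr, path) {
    df <- if (length(rows)) do.call(rbind, rows) else hdr
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(grows, hdr_g, paths["genotypes"])
  wt(arows, hdr_c, paths["calls_a"])
  wt(brows, hdr_c, paths["calls_b"])
  ped <- do.call(rbind, prows)
  utils::write.table(ped, paths["pedigree"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}
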