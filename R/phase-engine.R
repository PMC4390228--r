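# Family phasing engine.
#
# For one CNV region, every combination of parental phases (one per
# parent) and per-child gamete pairings is scored by the lexicographic
# parsimony criterion (number of unexplainable member x marker genotypes,
# then number of non-Mendelian events).  All co-optimal family solutions
# are reported; a region is unambiguous when exactly one solution remains
# after equivalence collapse.  Mendelian pairings are tried first per
# child and the non-Mendelian gamete space is expanded only when they
# cannot fully explain that child, which never changes the optimum: a
# zero-unexplained all-Mendelian child scores (0, 0) and no pairing can
# beat it.

.EVENTS_NONMEND <- c("DENOVO_DELETION", "DENOVO_DUP", "UPD_ISO", "UPD_HETERO")

.scheme <- function(event, cn, nb, src) {
  list(event = event, cn = as.integer(cn), nb = as.integer(nb),
       src = as.integer(src))
}

.lex_cmp <- function(a, b) {
  if (a[1] != b[1]) return(sign(a[1] - b[1]))
  sign(a[2] - b[2])
}

# All haplotypes of `phase` that could have produced a gamete with the
# given event and content.  Used to make the recorded sources canonical:
# identical haplotypes or indistinguishable sources collapse to the same
# candidate set whichever one actually generated the gamete.
.compatible_sources <- function(phase, event, gcn, gnb) {
  src <- integer(0)
  for (i in 1:2) {
    hcn <- phase$cn[i]; hnb <- phase$nb[i, ]
    ok <- switch(
      event,
      MENDELIAN = hcn == gcn && all(hnb == gnb),
      DENOVO_DELETION = hcn > gcn && all(gnb <= hnb) &&
        all((gcn - gnb) <= (hcn - hnb)),
      DENOVO_DUP = length(.dup_modes(phase, i, gcn, gnb)) > 0L,
      UPD_ISO = (2L * hcn == gcn) && all(2L * hnb == gnb),
      FALSE)
    if (isTRUE(ok)) src <- c(src, i)
  }
  src
}

# Which duplication modes ("intra", "inter") are consistent with source
# haplotype i of `phase` producing a gamete of (gcn, gnb): every extra
# allele must be drawable from the mode haplotype's allele types at every
# marker.
.dup_modes <- function(phase, i, gcn, gnb) {
  hcn <- phase$cn[i]; hnb <- phase$nb[i, ]
  ext <- gcn - hcn
  if (ext < 1L || hcn < 1L || gcn > 3L) return(character(0))
  d <- gnb - hnb
  if (any(d < 0L | d > ext)) return(character(0))
  mode_ok <- function(mi) {
    mcn <- phase$cn[mi]; mnb <- phase$nb[mi, ]
    if (mcn < 1L) return(FALSE)
    all((d == 0L | mnb >= 1L) & (d == ext | (mcn - mnb) >= 1L))
  }
  modes <- character(0)
  if (mode_ok(i)) modes <- c(modes, "intra")
  if (mode_ok(3L - i)) modes <- c(modes, "inter")
  modes
}

.phase_hap_key <- function(phase, i) {
  paste(phase$cn[i], paste(phase$nb[i, ], collapse = ","), sep = ":")
}

.phase_key <- function(phase) {
  paste(.phase_hap_key(phase, 1), .phase_hap_key(phase, 2), sep = "|")
}

#' Canonicalize a family solution
#'
#' Orders each parent's haplotype pair canonically (by haploid copy
#' number, then allele content) and rewrites every gamete scheme's source
#' haplotypes as the full set of haplotypes compatible with its event and
#' content, so that solutions identical up to hap1/hap2 relabeling or
#' permutation of identical haplotypes serialize identically.
#'
#' @param sol A family solution.
#' @return The canonicalized solution.
#' @export
canonical_solution <- function(sol) {
  for (p in c("father", "mother")) {
    ph <- sol[[p]]
    k1 <- c(ph$cn[1], ph$nb[1, ]); k2 <- c(ph$cn[2], ph$nb[2, ])
    if (!.lex_leq(k1, k2)) {
      ph$cn <- ph$cn[2:1]
      ph$nb <- ph$nb[2:1, , drop = FALSE]
      sol[[p]] <- ph
    }
    for (cid in names(sol$schemes)) {
      sc <- sol$schemes[[cid]][[p]]
      sc$src <- switch(sc$event,
                       UPD_HETERO = c(1L, 2L),
                       ABSENT = integer(0),
                       UNEXPLAINED = integer(0),
                       .compatible_sources(ph, sc$event, sc$cn, sc$nb))
      sol$schemes[[cid]][[p]] <- sc
    }
  }
  sol
}

#' Canonical serialization key of a family solution
#'
#' Two solutions are equivalent (and collapse to one) iff their keys are
#' equal.
#'
#' @param sol A family solution.
#' @return A single string.
#' @export
solution_key <- function(sol) {
  sol <- canonical_solution(sol)
  sstr <- function(sc) paste(sc$event, sc$cn, paste(sc$nb, collapse = ","),
                             paste(sc$src, collapse = ""), sep = ";")
  kids <- vapply(names(sol$schemes), function(cid) {
    paste0(cid, "{", sstr(sol$schemes[[cid]]$father), "}{",
           sstr(sol$schemes[[cid]]$mother), "}")
  }, character(1))
  paste(.phase_key(sol$father), .phase_key(sol$mother),
        paste(kids, collapse = "&"), sep = "#")
}

#' Collapse equivalent family solutions
#'
#' Merges solutions identical up to within-parent haplotype relabeling and
#' permutation of identical haplotypes, keeping one canonical
#' representative per equivalence class, in deterministic (key) order.
#' Idempotent.
#'
#' @param solutions List of family solutions.
#' @return List of canonical representatives, sorted by key.
#' @export
collapse_equivalent_solutions <- function(solutions) {
  if (length(solutions) == 0L) return(solutions)
  canon <- lapply(solutions, canonical_solution)
  keys <- vapply(canon, solution_key, character(1))
  keep <- !duplicated(keys)
  canon <- canon[keep]; keys <- keys[keep]
  canon[order(keys)]
}

# uniparental-disomy pairings for one parent: the child receives both
# gametes from this parent (two copies of one haplotype for isodisomy,
# both haplotypes for heterodisomy) and nothing from the other.
.upd_candidates <- function(phase, child_cn, child_nb) {
  out <- list()
  seen <- character(0)
  for (i in 1:2) {
    if (2L * phase$cn[i] == child_cn) {
      nb2 <- 2L * phase$nb[i, ]
      key <- paste(nb2, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <-
        list(event = "UPD_ISO", cn = child_cn, nb = nb2, src = i,
             u = sum(nb2 != child_nb))
    }
  }
  if (sum(phase$cn) == child_cn) {
    nb2 <- as.integer(colSums(phase$nb))
    out[[length(out) + 1L]] <-
      list(event = "UPD_HETERO", cn = child_cn, nb = nb2, src = c(1L, 2L),
           u = sum(nb2 != child_nb))
  }
  out
}

# score all cn-compatible (father gamete, mother gamete) pairings
.score_pairings <- function(gf, gm, child_cn, child_nb) {
  if (length(gf) == 0L || length(gm) == 0L) {
    return(list(i = integer(0), j = integer(0), u = integer(0),
                e = integer(0)))
  }
  cnf <- vapply(gf, `[[`, integer(1), "cn")
  cnm <- vapply(gm, `[[`, integer(1), "cn")
  idx <- which(outer(cnf, cnm, "+") == child_cn, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(i = integer(0), j = integer(0), u = integer(0),
                e = integer(0)))
  }
  m <- length(child_nb)
  if (m == 0L) {
    u <- rep(0L, nrow(idx))
  } else {
    nbf <- matrix(unlist(lapply(gf, `[[`, "nb")), nrow = length(gf),
                  byrow = TRUE)
    nbm <- matrix(unlist(lapply(gm, `[[`, "nb")), nrow = length(gm),
                  byrow = TRUE)
    tgt <- matrix(child_nb, nrow = nrow(idx), ncol = m, byrow = TRUE)
    u <- as.integer(rowSums(
      (nbf[idx[, 1], , drop = FALSE] + nbm[idx[, 2], , drop = FALSE]) != tgt))
  }
  evf <- as.integer(vapply(gf, `[[`, character(1), "event") != "MENDELIAN")
  evm <- as.integer(vapply(gm, `[[`, character(1), "event") != "MENDELIAN")
  list(i = idx[, 1], j = idx[, 2], u = u, e = evf[idx[, 1]] + evm[idx[, 2]])
}

.unexplained_pair <- function(m) {
  list(father = .scheme("UNEXPLAINED", 0L, rep(0L, m), integer(0)),
       mother = .scheme("UNEXPLAINED", 0L, rep(0L, m), integer(0)))
}

# core per-child optimisation given both parent phases; gamete lists are
# supplied so phase_region can cache them across children and phase pairs
.explain_child_core <- function(child_cn, child_nb, pf, pm,
                                mend_f, mend_m, get_full_f, get_full_m,
                                config) {
  m <- length(child_nb)
  build <- function(gf_list, gm_list, sc, keep) {
    lapply(keep, function(k) {
      gfk <- gf_list[[sc$i[k]]]; gmk <- gm_list[[sc$j[k]]]
      list(father = .scheme(gfk$event, gfk$cn, gfk$nb, gfk$src),
           mother = .scheme(gmk$event, gmk$cn, gmk$nb, gmk$src))
    })
  }
  sc <- .score_pairings(mend_f, mend_m, child_cn, child_nb)
  if (length(sc$u) && min(sc$u) == 0L) {
    keep <- which(sc$u == 0L)
    return(list(u = 0L, e = 0L, pairings = build(mend_f, mend_m, sc, keep)))
  }
  if (!config$allow_nonmendelian) {
    if (length(sc$u) == 0L) {
      return(list(u = m, e = 0L, pairings = list(.unexplained_pair(m))))
    }
    best <- min(sc$u)
    keep <- which(sc$u == best)
    return(list(u = best, e = 0L, pairings = build(mend_f, mend_m, sc, keep)))
  }
  gf <- get_full_f(); gm <- get_full_m()
  sc <- .score_pairings(gf, gm, child_cn, child_nb)
  upd <- c(lapply(.upd_candidates(pf, child_cn, child_nb),
                  function(x) c(x, list(parent = "father"))),
           lapply(.upd_candidates(pm, child_cn, child_nb),
                  function(x) c(x, list(parent = "mother"))))
  upd_u <- vapply(upd, `[[`, integer(1), "u")
  upd_e <- rep(config$count_upd_as, length(upd))
  all_u <- c(sc$u, upd_u)
  all_e <- c(sc$e, upd_e)
  if (length(all_u) == 0L) {
    return(list(u = m, e = 0L, pairings = list(.unexplained_pair(m))))
  }
  bu <- min(all_u)
  be <- min(all_e[all_u == bu])
  pairings <- list()
  keep <- which(sc$u == bu & sc$e == be)
  if (length(keep)) pairings <- build(gf, gm, sc, keep)
  for (k in which(upd_u == bu & upd_e == be)) {
    cand <- upd[[k]]
    absent <- .scheme("ABSENT", 0L, rep(0L, m), integer(0))
    carrier <- .scheme(cand$event, cand$cn, cand$nb, cand$src)
    pairings[[length(pairings) + 1L]] <-
      if (cand$parent == "father") list(father = carrier, mother = absent)
      else list(father = absent, mother = carrier)
  }
  list(u = bu, e = be, pairings = pairings)
}

#' Explain one child under fixed parental phases
#'
#' Finds all lexicographically co-optimal gamete pairings (one gamete per
#' parent, or a uniparental-disomy pairing) whose per-marker allele-
#' multiset union reproduces the child's genotypes wherever possible.
#' Mendelian pairings are preferred: the non-Mendelian space is searched
#' only when no Mendelian pairing explains every marker.
#'
#' @param child_cn Diploid copy number of the child over the region.
#' @param child_nb Integer vector of the child's per-marker B counts.
#' @param father_phase,mother_phase Phases from
#'   [enumerate_parent_phases()].
#' @param config A [phasing_config()].
#' @return A list with `u` (unexplained markers), `e` (non-Mendelian
#'   events) and `pairings`, a list of co-optimal scheme pairs
#'   (`father`/`mother` schemes with `event`, `cn`, `nb`, `src`).
#' @export
explain_child <- function(child_cn, child_nb, father_phase, mother_phase,
                          config = phasing_config()) {
  child_nb <- as.integer(child_nb)
  mend_f <- enumerate_gametes(father_phase, FALSE, config)
  mend_m <- enumerate_gametes(mother_phase, FALSE, config)
  .explain_child_core(
    as.integer(child_cn), child_nb, father_phase, mother_phase,
    mend_f, mend_m,
    function() enumerate_gametes(father_phase, TRUE, config),
    function() enumerate_gametes(mother_phase, TRUE, config),
    config)
}

#' Phase a family CNV region
#'
#' Runs the three-step search over one converged region: enumerate
#' parental haplotype combinations, then gamete formation schemes for
#' every child jointly, and report every co-optimal phased configuration
#' under the lexicographic parsimony score (unexplainable genotypes, then
#' non-Mendelian events).  De novo events in the reported solutions are
#' annotated with parent-of-origin and, for duplications, the
#' intra-/inter-chromosomal subtype.
#'
#' @param region A `cnv_region`; marker selection is applied if it has not
#'   been already.
#' @param family Optional family list; defaults to the family embedded in
#'   the region.
#' @param config A [phasing_config()].
#' @return A `phasing_result`: the region, the list of co-optimal
#'   canonical solutions, the shared `score` `(n_unexplained,
#'   n_nonmendelian)` and the `unambiguous` flag.
#' @export
phase_region <- function(region, family = NULL, config = phasing_config()) {
  stopifnot(inherits(region, "cnv_region"))
  if (!region$selected) region <- select_region_markers(region)
  fa <- region$father_id; mo <- region$mother_id
  kids <- if (is.null(family)) region$child_ids else family$child_ids
  m <- nrow(region$markers)
  cn <- region$member_cn
  nbm <- region$nb
  fphases <- enumerate_parent_phases(nbm[fa, ], cn[fa], config = config)
  mphases <- enumerate_parent_phases(nbm[mo, ], cn[mo], config = config)
  n_pairs <- length(fphases) * length(mphases)
  if (n_pairs > config$max_combinations) {
    stop("region ", region$region_id, ": search budget exceeded (",
         n_pairs, " phase pairs); consider subsampling markers")
  }
  mend_f <- lapply(fphases, enumerate_gametes, allow_nonmendelian = FALSE,
                   config = config)
  mend_m <- lapply(mphases, enumerate_gametes, allow_nonmendelian = FALSE,
                   config = config)
  full_f <- vector("list", length(fphases))
  full_m <- vector("list", length(mphases))
  best <- c(Inf, Inf)
  records <- list()
  for (i in seq_along(fphases)) {
    for (j in seq_along(mphases)) {
      get_ff <- function() {
        if (is.null(full_f[[i]])) {
          full_f[[i]] <<- enumerate_gametes(fphases[[i]], TRUE, config)
        }
        full_f[[i]]
      }
      get_fm <- function() {
        if (is.null(full_m[[j]])) {
          full_m[[j]] <<- enumerate_gametes(mphases[[j]], TRUE, config)
        }
        full_m[[j]]
      }
      tot_u <- 0L; tot_e <- 0L
      child_opts <- list()
      for (cid in kids) {
        res <- .explain_child_core(cn[cid], nbm[cid, ], fphases[[i]],
                                   mphases[[j]], mend_f[[i]], mend_m[[j]],
                                   get_ff, get_fm, config)
        tot_u <- tot_u + res$u
        tot_e <- tot_e + res$e
        child_opts[[cid]] <- res$pairings
      }
      score <- c(tot_u, tot_e)
      cmp <- .lex_cmp(score, best)
      if (cmp < 0) {
        best <- score
        records <- list()
      }
      if (cmp <= 0) {
        records[[length(records) + 1L]] <-
          list(i = i, j = j, child_opts = child_opts)
      }
    }
  }
  solutions <- list()
  n_sol <- 0
  for (rec in records) {
    counts <- vapply(rec$child_opts, length, integer(1))
    n_sol <- n_sol + prod(counts)
    if (n_sol > config$max_combinations) {
      stop("region ", region$region_id,
           ": search budget exceeded while assembling co-optimal solutions")
    }
    grid <- .combo_grid(lapply(counts, seq_len), config$max_combinations,
                        "solution assembly")
    for (r in seq_len(nrow(grid))) {
      schemes <- stats::setNames(vector("list", length(kids)), kids)
      for (k in seq_along(kids)) {
        schemes[[kids[k]]] <- rec$child_opts[[kids[k]]][[grid[r, k]]]
      }
      solutions[[length(solutions) + 1L]] <-
        list(father = fphases[[rec$i]], mother = mphases[[rec$j]],
             schemes = schemes)
    }
  }
  solutions <- collapse_equivalent_solutions(solutions)
  solutions <- lapply(solutions, .annotate_solution)
  structure(list(region = region,
                 region_id = region$region_id,
                 family_id = region$family_id,
                 solutions = solutions,
                 score = as.integer(best),
                 unambiguous = length(solutions) == 1L,
                 n_solutions = length(solutions)),
            class = "phasing_result")
}

#' Classify a de novo event within a solution
#'
#' Determines the parent-of-origin of a de novo deletion or duplication
#' scheme (undetermined when the two parents' phases are indistinguishable
#' at every marker) and, for duplications, whether the extra allele copies
#' were drawn from the source haplotype itself (`DENOVO_DUP_INTRA`), from
#' the other homolog (`DENOVO_DUP_INTER`), or either
#' (`DENOVO_DUP_AMBIG`).
#'
#' @param solution A family solution (from a `phasing_result`).
#' @param child_id Child identifier.
#' @param parent `"father"` or `"mother"`.
#' @return A list with `kind` and `parent_of_origin`.
#' @export
classify_de_novo <- function(solution, child_id, parent) {
  sc <- solution$schemes[[child_id]][[parent]]
  if (is.null(sc) || !sc$event %in% c("DENOVO_DELETION", "DENOVO_DUP"))
    stop("classify_de_novo requires a de novo deletion/duplication scheme")
  ph <- solution[[parent]]
  origin <- if (.phase_key(canonical_solution(solution)$father) ==
                .phase_key(canonical_solution(solution)$mother))
    "undetermined" else parent
  if (sc$event == "DENOVO_DELETION") {
    return(list(kind = "DENOVO_DELETION", parent_of_origin = origin))
  }
  srcs <- .compatible_sources(ph, "DENOVO_DUP", sc$cn, sc$nb)
  modes <- unique(unlist(lapply(srcs, function(i)
    .dup_modes(ph, i, sc$cn, sc$nb))))
  kind <- if (setequal(modes, "intra")) "DENOVO_DUP_INTRA"
  else if (setequal(modes, "inter")) "DENOVO_DUP_INTER"
  else "DENOVO_DUP_AMBIG"
  list(kind = kind, parent_of_origin = origin)
}

.annotate_solution <- function(sol) {
  for (cid in names(sol$schemes)) {
    for (p in c("father", "mother")) {
      sc <- sol$schemes[[cid]][[p]]
      if (sc$event %in% c("DENOVO_DELETION", "DENOVO_DUP")) {
        cl <- classify_de_novo(sol, cid, p)
        sc$subtype <- cl$kind
        sc$parent_origin <- cl$parent_of_origin
        sol$schemes[[cid]][[p]] <- sc
      }
    }
  }
  sol
}

#' @export
print.phasing_result <- function(x, ...) {
  cat("<phasing_result> ", x$region_id, ": ", x$n_solutions,
      " co-optimal solution(s), score (unexplained=", x$score[1],
      ", non-Mendelian=", x$score[2], "), ",
      if (x$unambiguous) "unambiguous" else "ambiguous", "\n", sep = "")
  if (x$n_solutions >= 1L) {
    sol <- x$solutions[[1]]
    for (p in c("father", "mother")) {
      ph <- sol[[p]]
      haps <- vapply(1:2, function(i) {
        if (ncol(ph$nb) == 0L) paste0("cn=", ph$cn[i])
        else paste0("cn=", ph$cn[i], " [",
                    paste(format_genotype(rep(ph$cn[i], ncol(ph$nb)),
                                          ph$nb[i, ]), collapse = " "), "]")
      }, character(1))
      cat("  ", p, ": ", haps[1], " / ", haps[2], "\n", sep = "")
    }
    for (cid in names(sol$schemes)) {
      ev <- vapply(c("father", "mother"), function(p) {
        s <- sol$schemes[[cid]][[p]]
        paste0(p, ":", if (!is.null(s$subtype)) s$subtype else s$event)
      }, character(1))
      cat("  child ", cid, ": ", paste(ev, collapse = "  "), "\n", sep = "")
    }
  }
  invisible(x)
}
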