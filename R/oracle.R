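# Brute-force reference implementation.
#
# Validates the phasing engine on small regions by enumerating the full
# solution space a second, independent way: allele multisets are explicit
# sorted character vectors, parental splits are enumerated in both orders
# and deduplicated afterwards, and the non-Mendelian gamete space is
# always generated in full (no Mendelian fast path).  Only the final
# canonical serialization is shared with the engine so that solution sets
# can be compared.

# -- multiset helpers on character vectors -------------------------------

.ms_sub <- function(tuple, k) {
  # distinct sub-multisets of size k, each a sorted character vector
  if (k == 0L) return(list(character(0)))
  if (k > length(tuple)) return(list())
  idx <- utils::combn(seq_along(tuple), k, simplify = FALSE)
  subs <- lapply(idx, function(i) sort(tuple[i]))
  subs[!duplicated(vapply(subs, paste, character(1), collapse = ""))]
}

.ms_extras <- function(types, k) {
  # distinct multisets of size k drawn (with repetition) from allele types
  if (k == 0L) return(list(character(0)))
  if (length(types) == 0L) return(list())
  if (k == 1L) return(lapply(types, identity))
  grids <- expand.grid(rep(list(types), k), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grids)), function(r) sort(unlist(grids[r, ])))
  out[!duplicated(vapply(out, paste, character(1), collapse = ""))]
}

.tuples_cartesian <- function(options_per_marker, cap) {
  # all ways of picking one tuple per marker
  n <- prod(vapply(options_per_marker, length, numeric(1)))
  if (n == 0) return(list())
  if (n > cap) stop("oracle cap exceeded")
  out <- list(list())
  for (opts in options_per_marker) {
    out <- unlist(lapply(out, function(prefix) {
      lapply(opts, function(o) c(prefix, list(o)))
    }), recursive = FALSE)
  }
  out
}

.hap_str <- function(cn, tuples) {
  paste(cn, paste(vapply(tuples, paste, character(1), collapse = ""),
                  collapse = "_"), sep = ":")
}

# -- enumeration ---------------------------------------------------------

.oracle_phases <- function(geno_tuples, cn, config, cap) {
  splits <- cn_splits_for(cn, config)
  ordered <- unique(do.call(c, lapply(splits, function(s) {
    if (s[1] == s[2]) list(s) else list(s, rev(s))
  })))
  phases <- list()
  seen <- character(0)
  for (s in ordered) {
    opts <- lapply(geno_tuples, function(tu) .ms_sub(tu, s[1]))
    for (h1 in .tuples_cartesian(opts, cap)) {
      h2 <- lapply(seq_along(geno_tuples), function(j) {
        tu <- geno_tuples[[j]]
        for (x in h1[[j]]) tu <- tu[-match(x, tu)]
        sort(tu)
      })
      key <- paste(sort(c(.hap_str(s[1], h1), .hap_str(s[2], h2))),
                   collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      phases[[length(phases) + 1L]] <-
        list(cn = c(s[1], s[2]), haps = list(h1, h2))
    }
  }
  phases
}

.oracle_gametes <- function(phase, allow_nonmendelian, config, cap) {
  m <- length(phase$haps[[1]])
  out <- list()
  seen <- character(0)
  add <- function(cn, tuples, event) {
    key <- paste(event, .hap_str(cn, tuples))
    if (key %in% seen) return()
    seen <<- c(seen, key)
    out[[length(out) + 1L]] <<- list(cn = cn, tuples = tuples, event = event)
  }
  for (i in 1:2) add(phase$cn[i], phase$haps[[i]], "MENDELIAN")
  if (allow_nonmendelian) {
    for (i in 1:2) {
      hcn <- phase$cn[i]; hap <- phase$haps[[i]]
      if (hcn >= 1L) {
        for (tgt in 0:(hcn - 1L)) {
          opts <- lapply(hap, function(tu) .ms_sub(tu, tgt))
          for (g in .tuples_cartesian(opts, cap)) {
            add(tgt, g, "DENOVO_DELETION")
          }
        }
      }
      exts <- if (config$allow_multistep_dup) 1:2 else 1L
      for (ext in exts) {
        if (hcn < 1L || hcn + ext > 3L) next
        for (mode in 1:2) {
          mh <- phase$haps[[if (mode == 1L) i else 3L - i]]
          if (phase$cn[if (mode == 1L) i else 3L - i] < 1L) next
          opts <- lapply(seq_len(m), function(j) {
            lapply(.ms_extras(unique(mh[[j]]), ext),
                   function(x) sort(c(hap[[j]], x)))
          })
          for (g in .tuples_cartesian(opts, cap)) {
            add(hcn + ext, g, "DENOVO_DUP")
          }
        }
      }
    }
  }
  out
}

.oracle_upd <- function(phase, child_cn) {
  out <- list()
  seen <- character(0)
  for (i in 1:2) {
    if (2L * phase$cn[i] == child_cn) {
      tuples <- lapply(phase$haps[[i]], function(tu) sort(c(tu, tu)))
      key <- .hap_str(child_cn, tuples)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <-
        list(cn = child_cn, tuples = tuples, event = "UPD_ISO", src = i)
    }
  }
  if (sum(phase$cn) == child_cn) {
    tuples <- lapply(seq_along(phase$haps[[1]]), function(j) {
      sort(c(phase$haps[[1]][[j]], phase$haps[[2]][[j]]))
    })
    out[[length(out) + 1L]] <-
      list(cn = child_cn, tuples = tuples, event = "UPD_HETERO",
           src = c(1L, 2L))
  }
  out
}

.tuple_counts <- function(tuples_list, m) {
  # rows = gametes; per-marker A and B counts
  na <- matrix(0L, nrow = length(tuples_list), ncol = m)
  nb <- matrix(0L, nrow = length(tuples_list), ncol = m)
  for (r in seq_along(tuples_list)) {
    for (j in seq_len(m)) {
      tu <- tuples_list[[r]][[j]]
      nb[r, j] <- sum(tu == "B")
      na[r, j] <- length(tu) - nb[r, j]
    }
  }
  list(na = na, nb = nb)
}

.oracle_to_scheme <- function(g) {
  m <- length(g$tuples)
  nb <- vapply(seq_len(m), function(j) sum(g$tuples[[j]] == "B"), integer(1))
  .scheme(g$event, g$cn, nb, integer(0))
}

.oracle_phase_to_engine <- function(phase) {
  m <- length(phase$haps[[1]])
  nb <- matrix(0L, nrow = 2L, ncol = m)
  for (i in 1:2) {
    for (j in seq_len(m)) nb[i, j] <- sum(phase$haps[[i]][[j]] == "B")
  }
  list(cn = as.integer(phase$cn), nb = nb)
}

# -- the oracle ----------------------------------------------------------

#' Brute-force phasing oracle
#'
#' Exhaustively enumerates every parental phase pair and every per-child
#' gamete pairing (always including the non-Mendelian space when enabled)
#' and scores them with the same lexicographic parsimony criterion as
#' [phase_region()], through an independent character-multiset code path.
#' Intended for validating the engine on small regions; refuses instances
#' whose enumeration exceeds `hard_cap`.
#'
#' @param region A `cnv_region` (marker selection applied if needed).
#' @param family Optional family list (defaults to the region's).
#' @param config A [phasing_config()].
#' @param hard_cap Refusal threshold on any single enumeration product.
#' @return A `phasing_result` with canonical co-optimal solutions.
#' @export
brute_force_phase <- function(region, family = NULL,
                              config = phasing_config(), hard_cap = 2e5) {
  stopifnot(inherits(region, "cnv_region"))
  if (!region$selected) region <- select_region_markers(region)
  fa <- region$father_id; mo <- region$mother_id
  kids <- if (is.null(family)) region$child_ids else family$child_ids
  m <- nrow(region$markers)
  cn <- region$member_cn
  tuples_of <- function(member) {
    lapply(seq_len(m), function(j) {
      nb <- region$nb[member, j]; sz <- region$size[member, j]
      sort(c(rep("A", sz - nb), rep("B", nb)))
    })
  }
  fph <- .oracle_phases(tuples_of(fa), cn[fa], config, hard_cap)
  mph <- .oracle_phases(tuples_of(mo), cn[mo], config, hard_cap)
  if (length(fph) * length(mph) > hard_cap) stop("oracle cap exceeded")
  child_tuples <- lapply(kids, tuples_of)
  names(child_tuples) <- kids
  child_counts <- lapply(child_tuples, function(tt) {
    nb <- vapply(tt, function(tu) sum(tu == "B"), integer(1))
    na <- vapply(tt, length, integer(1)) - nb
    list(na = na, nb = nb)
  })
  gam_cache_f <- stats::setNames(vector("list", length(fph)), NULL)
  gam_cache_m <- stats::setNames(vector("list", length(mph)), NULL)
  best <- c(Inf, Inf)
  records <- list()
  for (i in seq_along(fph)) {
    if (is.null(gam_cache_f[i][[1]])) {
      gam_cache_f[[i]] <- .oracle_gametes(fph[[i]],
                                          config$allow_nonmendelian,
                                          config, hard_cap)
    }
    gf <- gam_cache_f[[i]]
    cf <- .tuple_counts(lapply(gf, `[[`, "tuples"), m)
    cnf <- vapply(gf, `[[`, integer(1), "cn")
    evf <- as.integer(vapply(gf, `[[`, character(1), "event") != "MENDELIAN")
    for (j in seq_along(mph)) {
      if (is.null(gam_cache_m[j][[1]])) {
        gam_cache_m[[j]] <- .oracle_gametes(mph[[j]],
                                            config$allow_nonmendelian,
                                            config, hard_cap)
      }
      gm <- gam_cache_m[[j]]
      cm <- .tuple_counts(lapply(gm, `[[`, "tuples"), m)
      cnm <- vapply(gm, `[[`, integer(1), "cn")
      evm <- as.integer(vapply(gm, `[[`, character(1), "event") !=
                          "MENDELIAN")
      tot <- c(0L, 0L)
      child_opts <- list()
      for (cid in kids) {
        ccn <- cn[cid]
        cc <- child_counts[[cid]]
        idx <- which(outer(cnf, cnm, "+") == ccn, arr.ind = TRUE)
        cand_u <- integer(0); cand_e <- integer(0)
        if (nrow(idx)) {
          if (m == 0L) {
            cand_u <- rep(0L, nrow(idx))
          } else {
            ta <- matrix(cc$na, nrow = nrow(idx), ncol = m, byrow = TRUE)
            tb <- matrix(cc$nb, nrow = nrow(idx), ncol = m, byrow = TRUE)
            cand_u <- as.integer(rowSums(
              (cf$na[idx[, 1], , drop = FALSE] +
                 cm$na[idx[, 2], , drop = FALSE] != ta) |
              (cf$nb[idx[, 1], , drop = FALSE] +
                 cm$nb[idx[, 2], , drop = FALSE] != tb)))
          }
          cand_e <- evf[idx[, 1]] + evm[idx[, 2]]
        }
        upd <- if (config$allow_nonmendelian) {
          c(lapply(.oracle_upd(fph[[i]], ccn),
                   function(x) c(x, list(parent = "father"))),
            lapply(.oracle_upd(mph[[j]], ccn),
                   function(x) c(x, list(parent = "mother"))))
        } else list()
        upd_u <- vapply(upd, function(x) {
          xc <- .tuple_counts(list(x$tuples), m)
          if (m == 0L) 0L else
            as.integer(sum(xc$na[1, ] != cc$na | xc$nb[1, ] != cc$nb))
        }, integer(1))
        upd_e <- rep(config$count_upd_as, length(upd))
        all_u <- c(cand_u, upd_u); all_e <- c(cand_e, upd_e)
        if (length(all_u) == 0L) {
          opt <- list(list(father = .scheme("UNEXPLAINED", 0L, rep(0L, m),
                                            integer(0)),
                           mother = .scheme("UNEXPLAINED", 0L, rep(0L, m),
                                            integer(0))))
          bu <- m; be <- 0L
        } else {
          bu <- min(all_u)
          be <- min(all_e[all_u == bu])
          opt <- list()
          for (k in which(cand_u == bu & cand_e == be)) {
            opt[[length(opt) + 1L]] <-
              list(father = .oracle_to_scheme(gf[[idx[k, 1]]]),
                   mother = .oracle_to_scheme(gm[[idx[k, 2]]]))
          }
          for (k in which(upd_u == bu & upd_e == be)) {
            x <- upd[[k]]
            carrier <- .oracle_to_scheme(x)
            absent <- .scheme("ABSENT", 0L, rep(0L, m), integer(0))
            opt[[length(opt) + 1L]] <-
              if (x$parent == "father")
                list(father = carrier, mother = absent)
              else list(father = absent, mother = carrier)
          }
        }
        tot <- tot + c(bu, be)
        child_opts[[cid]] <- opt
      }
      cmp <- .lex_cmp(tot, best)
      if (cmp < 0) { best <- tot; records <- list() }
      if (cmp <= 0) {
        records[[length(records) + 1L]] <-
          list(i = i, j = j, child_opts = child_opts)
      }
    }
  }
  solutions <- list()
  for (rec in records) {
    counts <- vapply(rec$child_opts, length, integer(1))
    if (prod(counts) > hard_cap) stop("oracle cap exceeded")
    combos <- .tuples_cartesian(lapply(counts, seq_len), hard_cap)
    for (combo in combos) {
      schemes <- stats::setNames(vector("list", length(kids)), kids)
      for (k in seq_along(kids)) {
        schemes[[kids[k]]] <- rec$child_opts[[kids[k]]][[combo[[k]]]]
      }
      solutions[[length(solutions) + 1L]] <-
        list(father = .oracle_phase_to_engine(fph[[rec$i]]),
             mother = .oracle_phase_to_engine(mph[[rec$j]]),
             schemes = schemes)
    }
  }
  solutions <- collapse_equivalent_solutions(solutions)
  solutions <- lapply(solutions, .annotate_solution)
  structure(list(region = region, region_id = region$region_id,
                 family_id = region$family_id, solutions = solutions,
                 score = as.integer(best),
                 unambiguous = length(solutions) == 1L,
                 n_solutions = length(solutions)),
            class = "phasing_result")
}
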