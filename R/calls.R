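# Call-level merging and filtering.
#
# Two independent callers' raw call sets are merged per individual by
# coordinate intersection of same-type (gain/loss) overlapping calls;
# confirmed calls may additionally be intersected with an external
# validated call set (coordinates of the internal call kept).  Confirmed
# calls are then filtered: autosomes only, length >= 1000 bp, LBF >= 5.
# Coordinates are 1-based inclusive; overlap means >= 1 shared bp.

.call_type <- function(cn) ifelse(cn > 2L, "gain", "loss")

.sex_chroms <- c("X", "Y", "chrX", "chrY", "23", "24")

#' Intersect two callers' CNV calls per individual
#'
#' For every pair of same-sample, same-chromosome calls from the two sets
#' that overlap by at least 1 bp and agree in type (both gains, `cn > 2`,
#' or both losses, `cn < 2`), the coordinate intersection is emitted as a
#' confirmed call.  The diploid copy number (and confidence score) are
#' taken from the first, primary caller; a cn discordance between the
#' callers (e.g. 3 vs 4, same type) is kept but logged via a message.
#' Calls matched by no call of the other set are dropped from the
#' confirmed set but remain available as raw single-caller calls for the
#' family-region exclusion rule.
#'
#' @param calls_a,calls_b Call data.frames as read by [read_cnv_calls()];
#'   `calls_a` is the primary caller.
#' @return A data.frame of confirmed calls in the same layout.
#' @export
intersect_caller_calls <- function(calls_a, calls_b) {
  out <- calls_a[0, , drop = FALSE]
  if (nrow(calls_a) == 0L || nrow(calls_b) == 0L) return(out)
  rows <- list()
  for (i in seq_len(nrow(calls_a))) {
    a <- calls_a[i, ]
    cand <- calls_b[calls_b$sample_id == a$sample_id &
                    calls_b$chrom == a$chrom &
                    calls_b$start <= a$end & calls_b$end >= a$start &
                    .call_type(calls_b$cn) == .call_type(a$cn), ,
                    drop = FALSE]
    if (nrow(cand) == 0L) next
    for (j in seq_len(nrow(cand))) {
      b <- cand[j, ]
      if (b$cn != a$cn) {
        message("cn discordance between callers for sample ", a$sample_id,
                " at ", a$chrom, ":", max(a$start, b$start), "-",
                min(a$end, b$end), " (", a$cn, " vs ", b$cn,
                "); keeping primary caller's cn")
      }
      r <- a
      r$start <- max(a$start, b$start)
      r$end <- min(a$end, b$end)
      r$length <- r$end - r$start + 1L
      r$caller <- paste0(a$caller, "+", b$caller)
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0L) return(out)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Confirm calls against an external validated call set
#'
#' Same overlap-and-type rule as [intersect_caller_calls()], but the
#' coordinates (and cn, confidence) of the internal call are preserved;
#' the external set only decides which internal calls survive.
#'
#' @param confirmed_calls Internal (already caller-intersected) calls.
#' @param external_calls External validated calls in the same layout.
#' @return The subset of `confirmed_calls` confirmed externally.
#' @export
confirm_with_external_calls <- function(confirmed_calls, external_calls) {
  if (nrow(confirmed_calls) == 0L || nrow(external_calls) == 0L) {
    return(confirmed_calls[0, , drop = FALSE])
  }
  keep <- logical(nrow(confirmed_calls))
  for (i in seq_len(nrow(confirmed_calls))) {
    a <- confirmed_calls[i, ]
    keep[i] <- any(external_calls$sample_id == a$sample_id &
                   external_calls$chrom == a$chrom &
                   external_calls$start <= a$end &
                   external_calls$end >= a$start &
                   .call_type(external_calls$cn) == .call_type(a$cn))
  }
  res <- confirmed_calls[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter confirmed CNV calls
#'
#' Removes calls i) on the X/Y chromosomes, ii) shorter than 1000 bp
#' (strict: length 1000 is kept), iii) with confidence score (LBF) below 5
#' (strict: 5.0 is kept).
#'
#' @param calls A call data.frame.
#' @return The filtered data.frame (idempotent).
#' @export
filter_calls <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  keep <- !(calls$chrom %in% .sex_chroms) &
    (calls$end - calls$start + 1L) >= 1000L &
    calls$lbf >= 5
  res <- calls[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
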