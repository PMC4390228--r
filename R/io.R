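# Input parsing: genotype tables, CNV call tables, pedigrees, sample QC.

#' Read a per-sample per-marker genotype table
#'
#' The table is the parsed form of QuantiSNP/PennCNV/Fawkes per-marker
#' output: tab-separated with header
#' `sample_id marker_id chrom pos genotype confidence`.  Genotype strings
#' are multiploid calls over `{A,B}` (`"-"` for copy number 0, `"NC"` for
#' no-call); confidence is a call probability in `[0,1]`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `sample_id`, `marker_id`, `chrom`,
#'   `pos`, `genotype` (canonicalized string), `size`, `nb`, `no_call`,
#'   `confidence`.
#' @export
read_genotype_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "marker_id", "chrom", "pos", "genotype", "confidence")
  if (!all(need %in% names(df))) {
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(data.frame(sample_id = character(), marker_id = character(),
                      chrom = character(), pos = integer(),
                      genotype = character(), size = integer(),
                      nb = integer(), no_call = logical(),
                      confidence = numeric()))
  }
  gt <- tryCatch(parse_genotype_string(df$genotype), error = function(e) {
    bad <- grepl("[^ABNC-]", toupper(trimws(df$genotype)))
    line <- if (any(bad)) which(bad)[1] + 1L else NA_integer_
    stop("genotype table ", path, ", line ", line, ": ", conditionMessage(e))
  })
  conf <- suppressWarnings(as.numeric(df$confidence))
  bad_conf <- is.na(conf) | conf < 0 | conf > 1
  if (any(bad_conf)) {
    stop("genotype table ", path, ", line ", which(bad_conf)[1] + 1L,
         ": confidence outside [0,1]: ", df$confidence[which(bad_conf)[1]])
  }
  data.frame(sample_id = df$sample_id, marker_id = df$marker_id,
             chrom = df$chrom, pos = as.integer(df$pos),
             genotype = format_genotype(gt$size, gt$nb),
             size = gt$size, nb = gt$nb, no_call = gt$no_call,
             confidence = conf)
}

#' Read a CNV call table
#'
#' Tab-separated with header
#' `sample_id chrom start end cn lbf caller n_markers`.  Coordinates are
#' 1-based and inclusive on both ends; `cn` is the diploid copy number of
#' the call and must be one of 0, 1, 3, 4 (the normal state 2 is not a
#' call); `lbf` is a non-negative confidence score (QuantiSNP log Bayes
#' Factor or equivalent).
#'
#' @param path Path to the TSV file.
#' @return A data.frame of validated calls with a `length` column
#'   (`end - start + 1`).
#' @export
read_cnv_calls <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "cn", "lbf", "caller",
            "n_markers")
  if (!all(need %in% names(df))) {
    stop("CNV call table must have columns: ", paste(need, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$cn <- as.integer(df$cn)
  df$lbf <- as.numeric(df$lbf)
  df$n_markers <- as.integer(df$n_markers)
  if (nrow(df)) {
    if (any(df$cn == 2L)) {
      stop("CNV call with cn = 2 (line ", which(df$cn == 2L)[1] + 1L,
           "): the normal diploid state is not a call")
    }
    if (any(df$cn < 0L | df$cn > 4L)) {
      stop("CNV call with diploid copy number outside 0-4 (line ",
           which(df$cn < 0L | df$cn > 4L)[1] + 1L, ")")
    }
    if (any(df$start > df$end)) {
      stop("CNV call with start > end (line ",
           which(df$start > df$end)[1] + 1L, ")")
    }
    if (any(is.na(df$lbf) | df$lbf < 0)) {
      stop("CNV call with missing or negative confidence score")
    }
  }
  df$length <- df$end - df$start + 1L
  df
}

#' Read a pedigree of nuclear families
#'
#' Six-column PED dialect (`family_id individual_id father_id mother_id sex
#' phenotype`, whitespace-separated, `0` for unknown parent).  Only
#' two-generation nuclear families are supported: every non-founder must
#' name two founders of the same family as parents, and each family must
#' contain exactly one parental pair.
#'
#' @param path Path to the PED file.
#' @return A list of families, each a list with `family_id`, `father_id`,
#'   `mother_id` and `child_ids` (ordered as in the file).
#' @export
read_pedigree <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 6L) stop("pedigree file must have 6 columns")
  names(df)[1:6] <- c("family_id", "individual_id", "father_id", "mother_id",
                      "sex", "phenotype")
  if (anyDuplicated(df$individual_id)) {
    stop("duplicate individual id in pedigree: ",
         df$individual_id[duplicated(df$individual_id)][1])
  }
  fams <- list()
  for (fid in unique(df$family_id)) {
    rows <- df[df$family_id == fid, , drop = FALSE]
    founder <- rows$father_id == "0" & rows$mother_id == "0"
    kids <- rows[!founder, , drop = FALSE]
    if (nrow(kids) == 0L) {
      stop("family ", fid, " has no children")
    }
    pairs <- unique(kids[, c("father_id", "mother_id")])
    if (nrow(pairs) > 1L) {
      stop("family ", fid, " has more than one parental pair; ",
           "only nuclear families are supported")
    }
    fa <- pairs$father_id[1]; mo <- pairs$mother_id[1]
    if (fa == mo) stop("family ", fid, ": father and mother ids coincide")
    for (p in c(fa, mo)) {
      if (!p %in% rows$individual_id) {
        stop("family ", fid, ": child references missing parent id ", p)
      }
      if (!founder[match(p, rows$individual_id)]) {
        stop("family ", fid, ": parent ", p, " is itself a child ",
             "(more than 2 generations; only nuclear families are supported)")
      }
    }
    fams[[fid]] <- list(family_id = fid, father_id = fa, mother_id = mo,
                        child_ids = kids$individual_id)
  }
  fams
}

#' Sample-level array quality filter
#'
#' Applies the standard PennCNV array quality thresholds: a sample passes
#' iff `lrr_sd <= 0.25`, `baf_sd <= 0.05`, `baf_drift <= 0.002` and
#' `|gcwf| <= 0.04` (all inclusive).  Samples with any missing metric are
#' flagged indeterminate and excluded with a warning.
#'
#' @param metrics A data.frame with columns `sample_id`, `lrr_sd`,
#'   `baf_sd`, `baf_drift`, `gcwf`.
#' @return The input with logical columns `pass` and `indeterminate`.
#' @export
sample_qc_filter <- function(metrics) {
  need <- c("sample_id", "lrr_sd", "baf_sd", "baf_drift", "gcwf")
  stopifnot(all(need %in% names(metrics)))
  m <- metrics
  ind <- !stats::complete.cases(m[, c("lrr_sd", "baf_sd", "baf_drift", "gcwf")])
  if (any(ind)) {
    warning("sample(s) with missing QC metrics excluded as indeterminate: ",
            paste(m$sample_id[ind], collapse = ", "))
  }
  pass <- !ind &
    m$lrr_sd <= 0.25 & m$baf_sd <= 0.05 &
    m$baf_drift <= 0.002 & abs(m$gcwf) <= 0.04
  m$pass <- pass & !ind
  m$indeterminate <- ind
  m
}
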