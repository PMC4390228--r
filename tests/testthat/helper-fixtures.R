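# Shared fixtures: regions are built in code from allele-count matrices.

# Build a cnv_region directly from per-member B-count matrix `nb`
# (rows = members, cols = markers) and constant member copy numbers.
make_region <- function(member_cn, nb, father, mother, kids,
                        conf = NULL, nocall = NULL, size = NULL,
                        chrom = "1", start = 1000L, end = 2000L,
                        pos = NULL, selected = TRUE) {
  members <- names(member_cn)
  m <- ncol(nb)
  dn <- list(members, colnames(nb))
  if (is.null(size)) {
    size <- matrix(rep(member_cn, m), length(members), m, dimnames = dn)
  }
  if (is.null(conf)) conf <- matrix(0.99, length(members), m,
                                    dimnames = dn)
  if (is.null(nocall)) nocall <- matrix(FALSE, length(members), m,
                                        dimnames = dn)
  if (is.null(pos)) pos <- start + seq_len(m) * 10L
  mk_ids <- if (is.null(colnames(nb))) sprintf("m%d", seq_len(m)) else
    colnames(nb)
  structure(list(
    region_id = paste0("fix_", chrom, "_", start),
    family_id = "FIX", chrom = chrom, start = start, end = end,
    father_id = father, mother_id = mother, child_ids = kids,
    member_cn = member_cn, carrier_parents = c("father", "mother")[
      c(member_cn[father] != 2L, member_cn[mother] != 2L)],
    markers = data.frame(marker_id = mk_ids, pos = pos),
    size = size, nb = nb, conf = conf, nocall = nocall,
    selected = selected, flag = ""), class = "cnv_region")
}

# Worked duplication family: father CN=2 (AA/AB/BB), mother CN=3 with a
# duplication-carrying haplotype that is heterozygous at marker 1 (the
# within-haplotype informative SNP); two children pin down the phase.
fig_dup_family_region <- function() {
  cn <- c(fa = 2L, mo = 3L, c1 = 3L, c2 = 2L)
  nb <- matrix(c(0L, 1L, 2L,
                 2L, 0L, 2L,
                 1L, 0L, 3L,
                 1L, 1L, 1L), 4, 3, byrow = TRUE,
               dimnames = list(c("fa", "mo", "c1", "c2"), paste0("m", 1:3)))
  make_region(cn, nb, "fa", "mo", c("c1", "c2"))
}

# De novo deletion trio with indistinguishable parental haplotypes:
# father AB, mother AB, child monoploid "A" -- the deletion can sit on
# either parental chromosome.
denovo_ambiguous_trio_region <- function() {
  cn <- c(fa = 2L, mo = 2L, ch = 1L)
  nb <- matrix(c(1L, 1L, 0L), 3, 1,
               dimnames = list(c("fa", "mo", "ch"), "m1"))
  make_region(cn, nb, "fa", "mo", "ch")
}

# De novo intra-chromosomal duplication on the paternal chromosome:
# father AA/AB, mother AA/AA, child CN=3 AAA/ABB.
denovo_intra_dup_trio_region <- function() {
  cn <- c(fa = 2L, mo = 2L, ch = 3L)
  nb <- matrix(c(0L, 1L,
                 0L, 0L,
                 0L, 2L), 3, 2, byrow = TRUE,
               dimnames = list(c("fa", "mo", "ch"), c("m1", "m2")))
  make_region(cn, nb, "fa", "mo", "ch")
}

# simulation parameter sets used across tests
sim_params_small <- function(...) {
  defaults <- list(
    n_families = 1, children_dist = c("1" = 0.6, "2" = 0.4),
    markers_range = 1:4, allele_freq = 0.5,
    carrier_config = c(A_del = 0.35, A_dup2 = 0.2, A_dup3 = 0.1,
                       B_del = 0.15, none = 0.2),
    event_rates = c(denovo_del = 0.15, denovo_dup_intra = 0.08,
                    denovo_dup_inter = 0.08, upd_iso = 0.04,
                    upd_hetero = 0.04))
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

random_family <- function(max_children = 2) {
  list(family_id = "F", father_id = "fa", mother_id = "mo",
       child_ids = paste0("c", seq_len(sample.int(max_children, 1))))
}

solution_keys <- function(result) {
  vapply(result$solutions, solution_key, character(1))
}
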