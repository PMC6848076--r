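#' Opsin gene sets
#'
#' The rod opsin, and the cone opsins partitioned by the photoreceptor type
#' that expresses them: SWS genes in single cones, RH2/LWS genes in double
#' cones (established by in-situ labelling).
#'
#' @name opsin_genes
#' @keywords internal
NULL

rod_gene <- "RH1"
single_cone_genes <- c("SWS1", "SWS2B")
double_cone_genes <- c("RH2B", "RH2A", "LWS")
cone_genes <- c(single_cone_genes, double_cone_genes)

as_opsin_counts <- function(x) {
  if (is.data.frame(x) && nrow(x) == 1) {
    keep <- intersect(names(x), c(rod_gene, cone_genes))
    x <- stats::setNames(as.numeric(x[1, keep]), keep)
  }
  if (!is.numeric(x) || is.null(names(x))) {
    stop("counts must be a named numeric vector (or one-row data frame) of opsin genes",
         call. = FALSE)
  }
  bad <- setdiff(names(x), c(rod_gene, cone_genes))
  if (length(bad)) {
    stop("unknown opsin gene(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(x < 0)) stop("opsin counts must be nonnegative", call. = FALSE)
  x
}

#' Rod versus cone expression split
#'
#' Fraction of total opsin expression attributable to the rod opsin (RH1)
#' versus all cone opsins.
#'
#' @param counts Named numeric vector of normalized expression values, names
#'   among RH1, SWS1, SWS2B, RH2B, RH2A, LWS.
#' @return Named vector `c(rod = ..., cone = ...)`, summing to 1.
#' @examples
#' rod_cone_split(c(RH1 = 50, SWS1 = 10, RH2B = 25, RH2A = 15))
#' @export
rod_cone_split <- function(counts) {
  counts <- as_opsin_counts(counts)
  total <- sum(counts)
  if (total <= 0) stop("total opsin expression is zero", call. = FALSE)
  rod <- sum(counts[names(counts) == rod_gene])
  c(rod = rod / total, cone = (total - rod) / total)
}

#' Cone opsin expression proportions
#'
#' Either each cone gene as a fraction of total cone expression
#' (`"all_cones"`), or normalized separately within the single-cone genes
#' (SWS1, SWS2B) and the double-cone genes (RH2B, RH2A, LWS)
#' (`"single_double_split"`), the two partitions in which cohort results are
#' conventionally reported.
#'
#' @param counts Named numeric vector of expression values (RH1 ignored).
#' @param mode `"all_cones"` or `"single_double_split"`.
#' @return For `"all_cones"`, a named proportion vector over the cone genes
#'   present (sums to 1). For the split mode, a list with simplex-valued
#'   elements `single` and `double`.
#' @examples
#' cone_proportions(c(SWS1 = 8, SWS2B = 2, RH2B = 25, RH2A = 20, LWS = 5),
#'                  mode = "single_double_split")
#' @export
cone_proportions <- function(counts, mode = c("all_cones", "single_double_split")) {
  mode <- match.arg(mode)
  counts <- as_opsin_counts(counts)
  counts <- counts[names(counts) != rod_gene]
  if (sum(counts) <= 0) stop("total cone expression is zero", call. = FALSE)
  if (mode == "all_cones") {
    return(counts / sum(counts))
  }
  sing <- counts[names(counts) %in% single_cone_genes]
  doub <- counts[names(counts) %in% double_cone_genes]
  if (!length(sing) || sum(sing) <= 0) {
    stop("no single-cone (SWS) expression; split mode undefined", call. = FALSE)
  }
  if (!length(doub) || sum(doub) <= 0) {
    stop("no double-cone (RH2/LWS) expression; split mode undefined", call. = FALSE)
  }
  list(single = sing / sum(sing), double = doub / sum(doub))
}

#' Normalize raw transcript counts by transcript length
#'
#' Helper for pipelines whose upstream counts are raw mapped reads: divides
#' by transcript length before proportions are formed.
#'
#' @param raw_counts Named numeric vector of raw counts.
#' @param lengths Named numeric vector of transcript lengths (same names).
#' @return Length-normalized expression values.
#' @export
length_normalize <- function(raw_counts, lengths) {
  if (!all(names(raw_counts) %in% names(lengths))) {
    stop("every gene needs a transcript length", call. = FALSE)
  }
  raw_counts / lengths[names(raw_counts)]
}

#' Read a cohort opsin expression table
#'
#' @param path CSV with columns individual, sex, size_cm and one column per
#'   opsin gene (RH1, SWS1, SWS2B, RH2B, RH2A, LWS).
#' @return Data frame.
#' @export
read_opsin_counts <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cohort summary of opsin expression proportions
#'
#' Computes per-individual proportions in every reporting mode (rod vs cone;
#' cone genes as a fraction of all cones; single- and double-cone genes
#' normalized separately) and returns the arithmetic mean and sample SD of
#' each across the cohort.
#'
#' @param cohort Data frame with one row per individual and one column per
#'   opsin gene; extra columns (individual, sex, size_cm) are carried along
#'   but not used.
#' @return Data frame with columns `mode`, `gene`, `mean`, `sd`, `n`.
#'   Proportions are on the 0--1 scale.
#' @export
cohort_summary <- function(cohort) {
  genes <- intersect(names(cohort), c(rod_gene, cone_genes))
  if (nrow(cohort) < 2) {
    stop("cohort summary needs at least 2 individuals (sample SD undefined)",
         call. = FALSE)
  }
  per_ind <- lapply(seq_len(nrow(cohort)), function(i) {
    x <- stats::setNames(as.numeric(cohort[i, genes]), genes)
    rc <- rod_cone_split(x)
    ac <- cone_proportions(x, "all_cones")
    sp <- cone_proportions(x, "single_double_split")
    data.frame(
      mode = c(rep("rod_vs_cone", 2),
               rep("all_cones", length(ac)),
               rep("single", length(sp$single)),
               rep("double", length(sp$double))),
      gene = c(names(rc), names(ac), names(sp$single), names(sp$double)),
      proportion = c(rc, ac, sp$single, sp$double))
  })
  long <- do.call(rbind, per_ind)
  agg <- stats::aggregate(proportion ~ mode + gene, data = long,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(mode = agg$mode, gene = agg$gene,
                    mean = agg$proportion[, "mean"],
                    sd = agg$proportion[, "sd"],
                    n = nrow(cohort))
  out[order(out$mode, out$gene), ]
}
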