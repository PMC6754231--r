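## Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a class so callers and the
#' pipeline can distinguish configuration errors from data errors.
#' @noRd
qg_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "qgscan_error")))
}

#' Validate a genotype matrix
#'
#' Genotypes are integer matrices, strains in rows and markers in columns,
#' values in {0, 1, 2} with NA for missing calls. Row and column names are
#' required and must be unique.
#' @noRd
check_genotypes <- function(g, arg = "genotypes") {
  if (!is.matrix(g) || !is.numeric(g))
    qg_stop(sprintf("%s must be a numeric matrix (strains x markers)", arg),
            "qgscan_format_error")
  if (is.null(rownames(g)) || is.null(colnames(g)))
    qg_stop(sprintf("%s must have strain rownames and marker colnames", arg),
            "qgscan_format_error")
  if (anyDuplicated(rownames(g)) || anyDuplicated(colnames(g)))
    qg_stop(sprintf("duplicate strain or marker names in %s", arg),
            "qgscan_format_error")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    qg_stop(sprintf("%s values must be 0, 1, 2 or NA", arg),
            "qgscan_format_error")
  invisible(g)
}

#' Validate a marker map
#' @noRd
check_marker_map <- function(map, markers = NULL) {
  need <- c("marker", "chrom", "bp", "cM")
  if (!is.data.frame(map) || !all(need %in% names(map)))
    qg_stop("marker map needs columns marker, chrom, bp, cM",
            "qgscan_format_error")
  if (anyDuplicated(map$marker))
    qg_stop("duplicate marker ids in map", "qgscan_format_error")
  if (any(map$bp < 0) || any(map$cM < 0))
    qg_stop("map positions must be nonnegative", "qgscan_format_error")
  if (!is.null(markers) && !identical(as.character(map$marker), as.character(markers)))
    qg_stop("marker map does not match genotype matrix columns",
            "qgscan_format_error")
  invisible(map)
}

#' Minor allele frequency per marker
#'
#' Allele frequency of the alternate allele is mean(dosage)/2 over
#' non-missing calls; MAF folds it to [0, 0.5]. Markers with no calls get NA.
#' @noRd
marker_maf <- function(g) {
  p <- colMeans(g, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Deterministic per-stage RNG substream
#'
#' Derives a 32-bit-safe seed from a global seed and a stage name so each
#' pipeline stage has its own reproducible stream regardless of which other
#' stages run.
#' @noRd
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

#' Linear-interpolation quantiles (type 7), exposed for group summaries
#' @noRd
quartiles <- function(x) unname(quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE))

## Wide phenotype access: long table -> named vector for one trait.
## Replicate-level rows are averaged per strain (weighting replicates
## equally, matching "average percentage over replicates").
#' Extract one trait from a long phenotype table as a named vector
#'
#' @param pheno data frame with columns strain, trait, value (and optionally
#'   replicate-level counts); multiple rows per strain are averaged.
#' @param trait trait name to extract.
#' @return named numeric vector, one element per strain.
#' @export
trait_vector <- function(pheno, trait) {
  if (!all(c("strain", "trait", "value") %in% names(pheno)))
    qg_stop("phenotype table needs columns strain, trait, value",
            "qgscan_format_error")
  sub <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!nrow(sub))
    qg_stop(sprintf("trait '%s' not present in phenotype table", trait),
            "qgscan_data_error")
  out <- tapply(sub$value, sub$strain, mean)
  setNames(as.numeric(out), names(out))
}

#' Align a named phenotype vector to genotype strains
#' @noRd
align_strains <- function(y, g) {
  if (is.null(names(y))) {
    if (length(y) != nrow(g))
      qg_stop("unnamed phenotype vector length must match strain count",
              "qgscan_data_error")
    names(y) <- rownames(g)
    return(y)
  }
  shared <- intersect(rownames(g), names(y))
  if (length(shared) < 2)
    qg_stop("fewer than two strains shared between phenotype and genotypes",
            "qgscan_data_error")
  y[shared]
}
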