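## Readers and writers for the formats the analyses exchange:
## vcftools 012 trios, a minimal GT-only VCF dialect, phenotype CSVs,
## marker-map TSVs and Newick trees, plus the stated QC filters.
## Readers reject inconsistent inputs rather than silently truncating.

#' Write a genotype matrix as a vcftools-style 012 trio
#'
#' Produces \code{<prefix>.012} (leading 0-based sample index column,
#' genotypes 0/1/2 with -1 for missing), \code{<prefix>.012.indv} and
#' \code{<prefix>.012.pos} (chromosome and physical position per marker).
#'
#' @param genotypes strains x markers matrix coded 0/1/2/NA.
#' @param map marker map aligned with the genotype columns.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_012_trio <- function(genotypes, map, prefix) {
  check_genotypes(genotypes)
  check_marker_map(map, colnames(genotypes))
  g <- genotypes
  g[is.na(g)] <- -1
  body <- cbind(seq_len(nrow(g)) - 1L, g)
  write.table(body, paste0(prefix, ".012"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(rownames(genotypes), paste0(prefix, ".012.indv"))
  write.table(map[, c("chrom", "bp")], paste0(prefix, ".012.pos"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read a vcftools 012 trio
#'
#' Reads \code{<prefix>.012}, \code{.012.indv} and \code{.012.pos};
#' -1 becomes NA. Marker ids are synthesized as \code{chrom:pos}. Round-trips
#' with \code{\link{write_012_trio}} bit-exactly. Genetic positions are not
#' stored in this format, so the returned map carries \code{cM = NA}; attach
#' them with \code{\link{read_marker_map}} output or
#' \code{\link{assign_cM_from_bp}}.
#'
#' @param prefix path prefix of the trio.
#' @return list with \code{genotypes} and \code{map}.
#' @export
read_012_trio <- function(prefix) {
  f012 <- paste0(prefix, ".012")
  findv <- paste0(prefix, ".012.indv")
  fpos <- paste0(prefix, ".012.pos")
  for (f in c(f012, findv, fpos))
    if (!file.exists(f))
      qg_stop(sprintf("missing file: %s", f), "qgscan_format_error")
  body <- as.matrix(read.table(f012, sep = "\t", header = FALSE))
  indv <- readLines(findv)
  pos <- read.table(fpos, sep = "\t", header = FALSE,
                    col.names = c("chrom", "bp"),
                    colClasses = c("character", "integer"))
  if (nrow(body) != length(indv))
    qg_stop(sprintf("%s has %d rows but %s lists %d individuals",
                    f012, nrow(body), findv, length(indv)),
            "qgscan_format_error")
  g <- body[, -1, drop = FALSE]
  if (ncol(g) != nrow(pos))
    qg_stop(sprintf("%s has %d marker columns but %s lists %d positions",
                    f012, ncol(g), fpos, nrow(pos)),
            "qgscan_format_error")
  g[g == -1] <- NA
  storage.mode(g) <- "double"
  marker <- paste(pos$chrom, pos$bp, sep = ":")
  dimnames(g) <- list(indv, marker)
  map <- data.frame(marker = marker, chrom = pos$chrom, bp = pos$bp,
                    cM = NA_real_, stringsAsFactors = FALSE)
  list(genotypes = g, map = map)
}

#' Assign genetic positions from physical positions
#'
#' When only physical coordinates are available (as in a 012 trio), genetic
#' positions are assigned at a constant rate per chromosome. The default
#' 250 kb/cM is a nematode-like genome average.
#'
#' @param map marker map with \code{bp} filled in.
#' @param bp_per_cM physical distance corresponding to 1 cM.
#' @return the map with \code{cM} replaced by \code{bp / bp_per_cM},
#'   chromosome-local.
#' @export
assign_cM_from_bp <- function(map, bp_per_cM = 250000) {
  check_marker_map(map)
  map$cM <- map$bp / bp_per_cM
  map
}

#' Write genotypes as a minimal GT-only VCF
#'
#' Diploid GT calls only: 0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./. .
#' REF/ALT alleles are taken from the map if present (columns ref/alt),
#' else written as A/T placeholders.
#'
#' @inheritParams write_012_trio
#' @param path output .vcf path.
#' @return the path, invisibly.
#' @export
write_vcf_minimal <- function(genotypes, map, path) {
  check_genotypes(genotypes)
  check_marker_map(map, colnames(genotypes))
  ref <- if (!is.null(map$ref)) map$ref else rep("A", nrow(map))
  alt <- if (!is.null(map$alt)) map$alt else rep("T", nrow(map))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(map), nrow(genotypes))
  ok <- !is.na(t(genotypes))
  gt[ok] <- gt_code[as.character(t(genotypes)[ok])]
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- cbind(map$chrom, map$bp, map$marker, ref, alt, ".", "PASS", ".",
                "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  write.table(body, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a minimal GT-only VCF
#'
#' Parses diploid GT calls: 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2,
#' ./. -> NA ('|' separators accepted). Multi-allelic records are skipped;
#' the count of skipped records is attached as attribute
#' \code{n_multiallelic_skipped} and reported via \code{message()}.
#'
#' @param path VCF path.
#' @return list with \code{genotypes} and \code{map} (cM = NA).
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path))
    qg_stop(sprintf("missing file: %s", path), "qgscan_format_error")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (!nrow(vcf@gt) || !"FORMAT" %in% colnames(vcf@gt))
    qg_stop("VCF must carry a FORMAT column and at least one sample",
            "qgscan_format_error")
  if (!all(grepl("(^|:)GT($|:)", vcf@gt[, "FORMAT"])))
    qg_stop("VCF record without GT in FORMAT", "qgscan_format_error")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_skip <- sum(multi)
  if (n_skip)
    message(sprintf("read_vcf_minimal: skipped %d multi-allelic record(s)", n_skip))
  keep <- !multi
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  code <- c(`0/0` = 0, `0|0` = 0, `0/1` = 1, `1/0` = 1, `0|1` = 1, `1|0` = 1,
            `1/1` = 2, `1|1` = 2, `./.` = NA, `.|.` = NA, `.` = NA)
  ok <- is.na(gt) | gt %in% names(code)
  if (!all(ok))
    qg_stop(sprintf("unsupported GT value '%s'", gt[!ok][1]),
            "qgscan_format_error")
  g <- matrix(unname(code[gt]), nrow = nrow(gt))
  g <- t(g)
  marker <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                   paste(fix[, "CHROM"], fix[, "POS"], sep = ":"), fix[, "ID"])
  dimnames(g) <- list(colnames(gt), marker)
  map <- data.frame(marker = marker, chrom = fix[, "CHROM"],
                    bp = as.integer(fix[, "POS"]), cM = NA_real_,
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  list(genotypes = g, map = map)
}

#' Quality-control filter: samples, then markers
#'
#' Applies the two stated exclusions in fixed order: first samples whose
#' missing-call fraction is strictly greater than \code{max_sample_missing},
#' then markers whose minor allele frequency (computed over the remaining
#' samples, missing calls excluded from the denominator) falls below
#' \code{min_maf}. The filter is idempotent on its own output.
#'
#' @param genotypes strains x markers matrix coded 0/1/2/NA.
#' @param max_sample_missing maximum tolerated missing fraction per sample
#'   (0.90 in the RIL GBS pipeline this mirrors).
#' @param min_maf minimum minor allele frequency (0.01 in that pipeline).
#' @return list with \code{genotypes} (filtered), \code{removed_samples},
#'   \code{removed_markers}, and a one-row \code{report} of counts.
#' @export
qc_filter <- function(genotypes, max_sample_missing = 0.90, min_maf = 0.01) {
  check_genotypes(genotypes)
  if (max_sample_missing < 0 || max_sample_missing > 1 ||
      min_maf < 0 || min_maf > 1)
    qg_stop("thresholds must lie in [0, 1]", "qgscan_config_error")
  miss <- rowMeans(is.na(genotypes))
  drop_s <- rownames(genotypes)[miss > max_sample_missing]
  g <- genotypes[setdiff(rownames(genotypes), drop_s), , drop = FALSE]
  if (!nrow(g))
    qg_stop("all samples removed by missingness filter", "qgscan_data_error")
  maf <- marker_maf(g)
  drop_m <- colnames(g)[is.na(maf) | maf < min_maf]
  g <- g[, setdiff(colnames(g), drop_m), drop = FALSE]
  list(genotypes = g,
       removed_samples = drop_s,
       removed_markers = drop_m,
       report = data.frame(n_samples_in = nrow(genotypes),
                           n_samples_removed = length(drop_s),
                           n_markers_in = ncol(genotypes),
                           n_markers_removed = length(drop_m),
                           max_sample_missing = max_sample_missing,
                           min_maf = min_maf))
}

#' Read / write phenotype tables
#'
#' Long-format CSV with columns strain, trait, value and optionally
#' n_scored, n_with_gut, replicate. When counts are present, each row's
#' value must equal n_with_gut / n_scored (checked to 1e-9) and
#' n_with_gut <= n_scored.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("strain", "trait", "value") %in% names(ph)))
    qg_stop("phenotype CSV needs columns strain, trait, value",
            "qgscan_format_error")
  if (any(ph$value < 0 | ph$value > 1, na.rm = TRUE))
    qg_stop("penetrance values must lie in [0, 1]", "qgscan_format_error")
  if (all(c("n_scored", "n_with_gut") %in% names(ph))) {
    ok <- is.na(ph$n_scored) |
      (ph$n_with_gut <= ph$n_scored &
         abs(ph$value - ph$n_with_gut / ph$n_scored) < 1e-9)
    if (!all(ok))
      qg_stop(sprintf("phenotype row %d: value inconsistent with counts",
                      which(!ok)[1]), "qgscan_format_error")
  }
  ph
}

#' @rdname read_phenotypes
#' @param pheno phenotype data frame to write.
#' @export
write_phenotypes <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write marker maps
#'
#' TSV with header columns marker, chrom, bp, cM. Within each chromosome,
#' genetic positions must be nondecreasing when sorted by physical position.
#'
#' @param path TSV path.
#' @return marker map data frame.
#' @export
read_marker_map <- function(path) {
  map <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  check_marker_map(map)
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    sub <- sub[order(sub$bp), ]
    if (is.unsorted(sub$cM, na.rm = TRUE))
      qg_stop(sprintf("chromosome %s: cM not monotone in bp", ch),
              "qgscan_format_error")
  }
  map
}

#' @rdname read_marker_map
#' @param map marker map to write.
#' @export
write_marker_map <- function(map, path) {
  check_marker_map(map)
  write.table(map, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over ape's Newick support; reading requires branch
#' lengths, which the phylogenetic-signal model needs.
#'
#' @param path Newick file path.
#' @return an \code{ape::phylo}.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr))
    qg_stop("could not parse Newick file", "qgscan_format_error")
  if (is.null(tr$edge.length))
    qg_stop("Newick tree must carry branch lengths", "qgscan_format_error")
  tr
}

#' @rdname read_newick
#' @param tree an \code{ape::phylo} to write.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
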