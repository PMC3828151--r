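# Shared data model: variant tables, haplotype panels, genetic maps,
# tract sets, IBD segment sets.
#
# Conventions used throughout the package:
#   * base-pair positions are 1-based inclusive internally; BED output is
#     0-based half-open;
#   * genetic positions are centiMorgans (cM); model-level lengths are
#     Morgans (1 M = 100 cM);
#   * a haplotype id is "<sample>_<phase>" with phase 0 or 1.

#' Build a variant table
#'
#' A variant table records the loci of a haplotype panel: chromosome,
#' physical position (1-based bp), genetic position (cM) and alleles.
#' Physical positions must be strictly increasing within a chromosome and
#' genetic positions non-decreasing.
#'
#' @param chrom Chromosome identifiers.
#' @param pos_bp Integer physical positions, 1-based.
#' @param pos_cM Genetic positions in cM (may be `NA` before interpolation).
#' @param ref,alt Single-character alleles.
#' @param id Variant ids; defaults to `chrom:pos_bp`.
#' @return A tibble with columns `chrom`, `pos_bp`, `pos_cM`, `ref`, `alt`,
#'   `id`.
#' @export
variant_table <- function(chrom, pos_bp, pos_cM = NA_real_, ref = "A",
                          alt = "G", id = NULL) {
  tb <- tibble::tibble(
    chrom = as.character(chrom),
    pos_bp = as.integer(pos_bp),
    pos_cM = as.numeric(pos_cM),
    ref = as.character(ref),
    alt = as.character(alt),
    id = if (is.null(id)) paste0(chrom, ":", pos_bp) else as.character(id)
  )
  validate_variant_table(tb)
  tb
}

validate_variant_table <- function(variants) {
  stopifnot(all(variants$pos_bp >= 1L))
  by_chr <- split(variants, variants$chrom)
  for (v in by_chr) {
    if (is.unsorted(v$pos_bp, strictly = TRUE)) {
      stop("pos_bp must be strictly increasing within chromosome ",
           v$chrom[1], call. = FALSE)
    }
    cm <- v$pos_cM[!is.na(v$pos_cM)]
    if (length(cm) > 1 && is.unsorted(cm)) {
      stop("pos_cM must be non-decreasing within chromosome ", v$chrom[1],
           call. = FALSE)
    }
  }
  invisible(variants)
}

#' Construct a phased haplotype panel
#'
#' The central genotype container: a 0/1 allele matrix with one row per
#' haplotype (two per sample), a variant table describing the columns, and a
#' sample-to-population label table. The panel must be complete; missingness
#' only ever arises downstream through ancestry masking.
#'
#' @param alleles Integer matrix of 0/1 alleles, haplotypes x variants.
#'   Row names are haplotype ids `"<sample>_<phase>"`.
#' @param variants A [variant_table()].
#' @param labels Tibble with columns `sample_id`, `population`.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, variants, labels) {
  stopifnot(is.matrix(alleles), ncol(alleles) == nrow(variants))
  if (anyNA(alleles)) stop("haplotype panel must have no missing entries")
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be 0/1")
  if (is.null(rownames(alleles))) stop("allele matrix needs haplotype ids as rownames")
  hap_ids <- rownames(alleles)
  samples <- sub("_[01]$", "", hap_ids)
  phase <- as.integer(sub("^.*_", "", hap_ids))
  if (nrow(alleles) != 2 * length(unique(samples))) {
    stop("panel must contain exactly two haplotypes per sample")
  }
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("sample_id", "population") %in% names(labels)))
  missing_lab <- setdiff(unique(samples), labels$sample_id)
  if (length(missing_lab)) {
    stop("no population label for sample(s): ",
         paste(missing_lab, collapse = ", "))
  }
  structure(
    list(
      alleles = alleles,
      haplotypes = tibble::tibble(hap_id = hap_ids, sample_id = samples,
                                  phase = phase),
      variants = variants,
      labels = labels
    ),
    class = "haplotype_panel"
  )
}

#' @exportS3Method base::print
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$alleles), " haplotypes x ",
      ncol(x$alleles), " variants, ",
      length(unique(x$labels$population)), " population(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

# population label per haplotype row, in row order
hap_populations <- function(panel) {
  lab <- setNames(panel$labels$population, panel$labels$sample_id)
  unname(lab[panel$haplotypes$sample_id])
}

#' Read phased haplotypes from a VCF file
#'
#' Parses a VCF with phased GT fields into a [haplotype_panel()]. Each
#' sample contributes two haplotype rows, in the phase order of the GT
#' field. Any unphased ("/") or missing genotype is an error: the panel
#' must be complete. Multi-allelic records are skipped with a warning.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @param labels Tibble mapping `sample_id` to `population`. If `NULL`, all
#'   samples are labelled `"unknown"`.
#' @return A [haplotype_panel()].
#' @export
read_phased_haplotypes <- function(path, labels = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  if (nrow(gt) == 0) stop("no biallelic records in ", path)
  if (anyNA(gt) || any(gt %in% c(".", "./.", ".|."))) {
    stop("missing GT in ", path, ": panel must be complete")
  }
  unph <- grepl("/", gt, fixed = TRUE)
  dim(unph) <- dim(gt)
  if (any(unph)) {
    bad <- which(unph, arr.ind = TRUE)[1, ]
    stop("unphased genotype at record ", fix$ID[bad[1]], " (",
         fix$CHROM[bad[1]], ":", fix$POS[bad[1]], "), sample ",
         colnames(gt)[bad[2]])
  }
  a0 <- matrix(as.integer(sub("\\|.*$", "", gt)), nrow = nrow(gt))
  a1 <- matrix(as.integer(sub("^.*\\|", "", gt)), nrow = nrow(gt))
  samples <- colnames(gt)
  n_var <- nrow(gt)
  alleles <- matrix(0L, nrow = 2 * length(samples), ncol = n_var)
  rn <- character(2 * length(samples))
  for (i in seq_along(samples)) {
    alleles[2 * i - 1, ] <- a0[, i]
    alleles[2 * i, ] <- a1[, i]
    rn[2 * i - 1] <- paste0(samples[i], "_0")
    rn[2 * i] <- paste0(samples[i], "_1")
  }
  rownames(alleles) <- rn
  variants <- variant_table(
    chrom = fix$CHROM, pos_bp = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  )
  if (is.null(labels)) {
    labels <- tibble::tibble(sample_id = samples, population = "unknown")
  }
  haplotype_panel(alleles, variants, labels)
}

#' Read a genetic map
#'
#' Three-column (chrom, bp, cM) whitespace-separated table, optional header.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `pos_bp`, `pos_cM`, sorted by
#'   chromosome and position.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\S+\\s+\\d+\\s+[-0-9.eE+]+\\s*$", first)
  tb <- readr::read_table(path, col_names = has_header,
                          show_col_types = FALSE, skip = 0)
  if (!has_header) names(tb) <- c("chrom", "pos_bp", "pos_cM")[seq_len(ncol(tb))]
  names(tb)[1:3] <- c("chrom", "pos_bp", "pos_cM")
  genetic_map(tb$chrom, tb$pos_bp, tb$pos_cM)
}

#' Build a genetic map from knot vectors
#'
#' @param chrom,pos_bp,pos_cM Knot coordinates; cM must be non-decreasing in
#'   bp within each chromosome.
#' @return Tibble of map knots.
#' @export
genetic_map <- function(chrom, pos_bp, pos_cM) {
  tb <- tibble::tibble(chrom = as.character(chrom),
                       pos_bp = as.numeric(pos_bp),
                       pos_cM = as.numeric(pos_cM)) |>
    dplyr::arrange(.data$chrom, .data$pos_bp)
  for (v in split(tb, tb$chrom)) {
    if (is.unsorted(v$pos_cM)) {
      stop("map cM must be non-decreasing within chromosome ", v$chrom[1])
    }
  }
  tb
}

#' Interpolate genetic positions for variants
#'
#' Linear interpolation of cM positions between flanking map knots;
#' positions outside the knot range are clamped to the end knots.
#'
#' @param variants A [variant_table()].
#' @param map A [genetic_map()].
#' @return The variant table with `pos_cM` filled in.
#' @export
interpolate_genetic_positions <- function(variants, map) {
  miss <- setdiff(unique(variants$chrom), unique(map$chrom))
  if (length(miss)) {
    stop("chromosome(s) absent from genetic map: ",
         paste(miss, collapse = ", "))
  }
  out <- variants
  for (chr in unique(variants$chrom)) {
    knots <- map[map$chrom == chr, ]
    idx <- which(variants$chrom == chr)
    if (nrow(knots) == 1) {
      out$pos_cM[idx] <- knots$pos_cM
    } else {
      out$pos_cM[idx] <- approx(knots$pos_bp, knots$pos_cM,
                                xout = variants$pos_bp[idx],
                                rule = 2, ties = "ordered")$y
    }
  }
  out
}

#' Construct a tract set
#'
#' Per-haplotype continuous ancestry intervals in genetic and physical
#' coordinates. Tracts of one haplotype on one chromosome must be
#' non-overlapping; `length_cM` is derived.
#'
#' @param hap_id,chrom,start_bp,end_bp,start_cM,end_cM,ancestry Vectors of
#'   equal length.
#' @param is_whole_chromosome Logical flag per tract.
#' @return Tibble of tract records with a `length_cM` column.
#' @export
tract_set <- function(hap_id, chrom, start_bp, end_bp, start_cM, end_cM,
                      ancestry, is_whole_chromosome = FALSE) {
  tb <- tibble::tibble(
    hap_id = as.character(hap_id), chrom = as.character(chrom),
    start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
    start_cM = as.numeric(start_cM), end_cM = as.numeric(end_cM),
    ancestry = as.character(ancestry),
    is_whole_chromosome = as.logical(is_whole_chromosome)
  )
  if (any(tb$end_cM <= tb$start_cM) || any(tb$end_bp <= tb$start_bp)) {
    stop("tract end must exceed start")
  }
  dplyr::mutate(tb, length_cM = .data$end_cM - .data$start_cM)
}

#' Write tracts as BED-like text
#'
#' One line per tract: chrom, 0-based half-open start, end,
#' `haplotype:ancestry` as name, and round(length_cM * 100) as score. A
#' header line is always written.
#'
#' @param tracts A [tract_set()].
#' @param path Output path.
#' @export
write_tracts_bed <- function(tracts, path) {
  header <- "#chrom\tstart\tend\tname\tscore\tstart_cM\tend_cM\twhole_chrom"
  lines <- character(0)
  if (nrow(tracts)) {
    lines <- sprintf(
      "%s\t%d\t%d\t%s:%s\t%d\t%.6f\t%.6f\t%d",
      tracts$chrom, as.integer(tracts$start_bp) - 1L,
      as.integer(tracts$end_bp), tracts$hap_id, tracts$ancestry,
      as.integer(round(tracts$length_cM * 100)),
      tracts$start_cM, tracts$end_cM, as.integer(tracts$is_whole_chromosome)
    )
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read tracts written by [write_tracts_bed()]
#'
#' @param path Input path.
#' @return A [tract_set()] tibble.
#' @export
read_tracts_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(tract_set(character(0), character(0), numeric(0), numeric(0),
                     numeric(0), numeric(0), character(0), logical(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- do.call(rbind, f)
  name <- f[, 4]
  sep <- regexpr(":[^:]*$", name)
  tract_set(
    hap_id = substr(name, 1, sep - 1), chrom = f[, 1],
    start_bp = as.numeric(f[, 2]) + 1, end_bp = as.numeric(f[, 3]),
    start_cM = as.numeric(f[, 6]), end_cM = as.numeric(f[, 7]),
    ancestry = substring(name, sep + 1),
    is_whole_chromosome = f[, 8] == "1"
  )
}

#' Read an IBD segment table
#'
#' Whitespace/tab-separated table with at least five columns: id1, id2,
#' chrom, start bp, end bp. Pair keys are normalised so id1 < id2
#' lexicographically, and segment length in Mb is computed.
#'
#' @param path File path.
#' @return Tibble with columns `id1`, `id2`, `chrom`, `start_bp`, `end_bp`,
#'   `length_Mb`.
#' @export
read_ibd_segments <- function(path) {
  tb <- readr::read_table(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(tb) < 5) stop("IBD table needs at least 5 columns")
  out <- tibble::tibble(
    id1 = as.character(tb[[1]]), id2 = as.character(tb[[2]]),
    chrom = as.character(tb[[3]]),
    start_bp = as.numeric(tb[[4]]), end_bp = as.numeric(tb[[5]])
  )
  bad <- which(out$end_bp <= out$start_bp)
  if (length(bad)) {
    stop("IBD segment end <= start at row ", bad[1])
  }
  if (any(out$id1 == out$id2)) stop("IBD segment with id1 == id2")
  swap <- out$id1 > out$id2
  tmp <- out$id1[swap]; out$id1[swap] <- out$id2[swap]; out$id2[swap] <- tmp
  dplyr::mutate(out, length_Mb = (.data$end_bp - .data$start_bp) / 1e6)
}
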