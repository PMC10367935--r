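#' Tumor-only candidate-mutation filtering for TMB
#'
#' Applies the three tumor-only filtering rules used for the TMB point
#' estimate:
#' \enumerate{
#'   \item population-database rule: any variant reported in gnomAD is
#'     excluded;
#'   \item allele-frequency window: variants with VAF in the closed interval
#'     \[0.45, 0.55\] are excluded when the sample's molecularly informed
#'     tumor content (MTC) is below 80\%; such variants are retained for the
#'     upper bound of the TMB estimate;
#'   \item clonality rule: only variants with VAF strictly greater than one
#'     fourth of the MTC are kept.
#' }
#' Together these remove false-positive germline variants (including those
#' in regions of loss of heterozygosity) regardless of their representation
#' in population databases.
#'
#' The VAF window is taken as closed at both endpoints, the conservative
#' (more filtering) reading.
#'
#' @param variants data.frame with columns `vaf` (fraction in \[0,1\]),
#'   `in_gnomad` (logical) and optionally `eligible` (logical, default all
#'   TRUE) and `variant_id`
#' @param mtc molecularly informed tumor content, fraction in (0, 1]
#' @return list with `point_set` and `upper_set`, both subsets of `variants`
#'   with input order preserved (`point_set` is a subset of `upper_set`)
#' @examples
#' v <- data.frame(vaf = c(.30, .50, .50, .10),
#'                 in_gnomad = c(FALSE, TRUE, FALSE, FALSE))
#' filter_candidate_mutations(v, mtc = 0.60)
#' @export
filter_candidate_mutations <- function(variants, mtc) {
  if (!is.data.frame(variants))
    stop_input("'variants' must be a data.frame")
  if (!is.numeric(mtc) || length(mtc) != 1 || is.na(mtc) ||
      mtc <= 0 || mtc > 1)
    stop_input("'mtc' must be a single fraction in (0, 1]")
  if (nrow(variants) == 0)
    return(list(point_set = variants, upper_set = variants))
  for (col in c("vaf", "in_gnomad"))
    if (is.null(variants[[col]]))
      stop_input("'variants' is missing column '%s'", col)
  vaf <- variants$vaf
  if (anyNA(vaf) || any(vaf < 0 | vaf > 1))
    stop_input("'vaf' values must lie in [0, 1]")
  eligible <- if (is.null(variants$eligible)) rep(TRUE, nrow(variants))
              else isTRUE_vec(variants$eligible)

  base_keep <- eligible & !isTRUE_vec(variants$in_gnomad) & vaf > mtc / 4
  in_window <- mtc < 0.80 & vaf >= 0.45 & vaf <= 0.55
  list(point_set = variants[base_keep & !in_window, , drop = FALSE],
       upper_set = variants[base_keep, , drop = FALSE])
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' TMB point estimate, upper bound and status
#'
#' Converts filtered mutation counts to mutations per megabase of panel
#' footprint. TMB-high is called at >= 10 Muts/Mb (inclusive); combined
#' MSI/TMB status is MSI/TMB-H when the sample is MSI-high or TMB-high.
#' The upper bound is count-based: the same normalization applied to the
#' filter set that retains the allele-frequency-window variants.
#'
#' @param point_count number of mutations passing all point-estimate filters
#' @param upper_count number of mutations in the upper-bound set
#'   (>= `point_count`)
#' @param panel_mb panel footprint in megabases (> 0; assay configuration,
#'   not printed on reports)
#' @param msi_high logical MSI status from the assay (upstream input)
#' @return list of class `tmb_result` with `point_estimate`, `upper_bound`
#'   (Muts/Mb), `tmb_high` and `combined_status` (`"MSI/TMB-H"` or
#'   `"MSS/TMB-L"`)
#' @export
compute_tmb <- function(point_count, upper_count, panel_mb, msi_high = FALSE) {
  if (!is.numeric(panel_mb) || length(panel_mb) != 1 || is.na(panel_mb) ||
      panel_mb <= 0)
    stop_input("'panel_mb' must be a single positive number")
  if (point_count < 0 || upper_count < point_count)
    stop_input("counts must satisfy 0 <= point_count <= upper_count")
  pe <- point_count / panel_mb
  ub <- upper_count / panel_mb
  high <- pe >= 10
  structure(list(point_estimate = pe,
                 upper_bound = ub,
                 tmb_high = high,
                 combined_status = if (high || isTRUE(msi_high)) "MSI/TMB-H"
                                   else "MSS/TMB-L"),
            class = "tmb_result")
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf("TMB %.2f Muts/Mb (upper bound %.2f); %s; %s\n",
              x$point_estimate, x$upper_bound,
              if (x$tmb_high) "TMB-H" else "TMB-L", x$combined_status))
  invisible(x)
}

#' Filter variants and compute TMB in one step
#'
#' @param variants variant table, see [filter_candidate_mutations()]
#' @param mtc molecularly informed tumor content in (0, 1]
#' @param panel_mb panel footprint in megabases
#' @param msi_high logical MSI status
#' @return a `tmb_result`, see [compute_tmb()]
#' @export
tmb_from_variants <- function(variants, mtc, panel_mb, msi_high = FALSE) {
  f <- filter_candidate_mutations(variants, mtc)
  compute_tmb(nrow(f$point_set), nrow(f$upper_set), panel_mb, msi_high)
}

#' Read a per-sample variant table
#'
#' Reads either a plain TSV/CSV with columns `variant_id`, `vaf`,
#' `in_gnomad` (and optionally `eligible`), or a VCF file. For VCF input the
#' VAF and gnomAD-membership flag are taken from configurable INFO fields
#' (requires the `vcfR` package).
#'
#' @param path file path (`.vcf`/`.vcf.gz` triggers VCF parsing)
#' @param vaf_field,gnomad_field INFO field names used for VCF input
#' @return data.frame with `variant_id`, `vaf`, `in_gnomad`, `eligible`
#' @export
read_variant_table <- function(path, vaf_field = "VAF",
                               gnomad_field = "GNOMAD") {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop_input("reading VCF input requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    info_num <- function(field) {
      suppressWarnings(as.numeric(vcfR::extract.info(v, element = field)))
    }
    vaf <- info_num(vaf_field)
    if (anyNA(vaf))
      stop_input("VCF INFO field '%s' missing or non-numeric", vaf_field)
    gn <- vcfR::extract.info(v, element = gnomad_field)
    fx <- vcfR::getFIX(v)
    data.frame(
      variant_id = paste(fx[, "CHROM"], fx[, "POS"], fx[, "REF"],
                         fx[, "ALT"], sep = ":"),
      vaf = vaf,
      in_gnomad = !is.na(gn) & gn %in% c("1", "TRUE", "T", "yes"),
      eligible = TRUE,
      stringsAsFactors = FALSE)
  } else {
    x <- read_table_auto(path)
    for (col in c("vaf", "in_gnomad"))
      if (is.null(x[[col]]))
        stop_input("variant table is missing column '%s'", col)
    if (is.null(x$variant_id)) x$variant_id <- seq_len(nrow(x))
    if (is.null(x$eligible)) x$eligible <- TRUE
    x$in_gnomad <- isTRUE_vec(x$in_gnomad)
    x$eligible <- isTRUE_vec(x$eligible)
    x
  }
}
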