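#' PLA puncta density
#'
#' Proximity-ligation-assay puncta per unit cell area (puncta/um^2).
#' Vectorized over cells.
#'
#' @param puncta_count non-negative integer counts.
#' @param cell_area_um2 cell areas (um^2), > 0.
#' @return Numeric densities (puncta/um^2).
#' @export
puncta_density <- function(puncta_count, cell_area_um2) {
  if (any(!is.finite(cell_area_um2)) || any(cell_area_um2 <= 0))
    stop("cell_area_um2 must be > 0")
  if (any(puncta_count < 0)) stop("puncta_count must be >= 0")
  puncta_count / cell_area_um2
}

#' Relative gene expression by the 2^-ddCt method
#'
#' For each sample, `dCt = Ct_target - Ct_reference` (reference gene, e.g.
#' GAPDH, run as internal control). `ddCt` subtracts the mean `dCt` of the
#' calibrator group per gene and the fold change is `2^-ddCt`, so the
#' calibrator group has geometric-mean fold 1 by construction. Samples
#' lacking a reference Ct are dropped with a warning.
#'
#' @param ct data frame with columns `sample_id`, `gene`, `ct`, `group`.
#' @param calibrator_group group label used as calibrator.
#' @param reference_gene reference gene name (default `"GAPDH"`).
#' @return List with `per_sample` (data frame: `sample_id`, `group`, `gene`,
#'   `delta_ct`, `ddct`, `fold`) and `per_group` (geometric-mean fold per
#'   group and gene).
#' @export
relative_expression <- function(ct, calibrator_group,
                                reference_gene = "GAPDH") {
  need <- c("sample_id", "gene", "ct", "group")
  stopifnot(is.data.frame(ct), all(need %in% names(ct)))
  if (!calibrator_group %in% ct$group)
    stop("calibrator_group not present in the table")
  ref <- ct[ct$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  tgt <- ct[ct$gene != reference_gene, ]
  if (nrow(tgt) == 0L) stop("no target genes in the table")
  merged <- merge(tgt, ref, by = "sample_id", all.x = TRUE)
  dropped <- unique(merged$sample_id[is.na(merged$ct_ref)])
  if (length(dropped)) {
    warning(sprintf("dropping %d sample(s) without a reference Ct: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    merged <- merged[!is.na(merged$ct_ref), ]
  }
  merged$delta_ct <- merged$ct - merged$ct_ref
  cal_mean <- tapply(merged$delta_ct[merged$group == calibrator_group],
                     merged$gene[merged$group == calibrator_group], mean)
  merged$ddct <- merged$delta_ct - as.numeric(cal_mean[merged$gene])
  merged$fold <- 2^(-merged$ddct)
  per_sample <- merged[order(merged$gene, merged$group, merged$sample_id),
                       c("sample_id", "group", "gene", "delta_ct", "ddct", "fold")]
  rownames(per_sample) <- NULL
  gm <- stats::aggregate(fold ~ group + gene, per_sample,
                         function(x) exp(mean(log(x))))
  names(gm)[3] <- "geom_mean_fold"
  list(per_sample = per_sample, per_group = gm)
}

#' Densitometry band normalization
#'
#' Immunoblot band intensity divided by a loading signal (a loading-control
#' band or total protein). When a logical `calibrator` vector is supplied,
#' ratios are additionally reported relative to the mean ratio of the
#' calibrator (control) lanes.
#'
#' @param band_intensity band intensities, >= 0.
#' @param loading_intensity loading-signal intensities, > 0.
#' @param calibrator optional logical vector marking control lanes.
#' @return Numeric ratios; with `calibrator`, a data frame with `ratio` and
#'   `relative` columns.
#' @export
densitometry_ratio <- function(band_intensity, loading_intensity,
                               calibrator = NULL) {
  if (any(!is.finite(loading_intensity)) || any(loading_intensity <= 0))
    stop("loading_intensity must be > 0")
  ratio <- band_intensity / loading_intensity
  if (is.null(calibrator)) return(ratio)
  stopifnot(is.logical(calibrator), length(calibrator) == length(ratio),
            any(calibrator))
  data.frame(ratio = ratio, relative = ratio / mean(ratio[calibrator]))
}
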