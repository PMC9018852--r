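#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot module spans along the genome
#'
#' One horizontal segment per called module, coloured by mean within-module
#' correlation.
#'
#' @param vcms a `vcm_set` tibble.
#' @return a ggplot.
#' @export
plot_module_map <- function(vcms) {
  ggplot2::ggplot(as_tibble(vcms),
                  ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                               y = .data$module_id, yend = .data$module_id,
                               colour = .data$mean_r)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom), scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "mean r") +
    ggplot2::theme_minimal()
}

#' Module activity by genotype dosage
#'
#' Boxplots of the aVCM score per genotype group, the standard QTL
#' visualisation.
#'
#' @param activity a `vcm_activity` score table.
#' @param genotypes genotype tibble (one variant row; dosage per sample).
#' @param variant_id which variant to plot (default: first row).
#' @return a ggplot.
#' @export
plot_avcm_by_genotype <- function(activity, genotypes, variant_id = NULL) {
  g <- as_tibble(genotypes)
  if (!is.null(variant_id)) g <- filter(g, .data$variant_id == !!variant_id)
  dos <- tidyr::pivot_longer(g[1, setdiff(names(g), c("variant_id", "chrom",
                                                      "pos", "ref", "alt"))],
                             everything(), names_to = "sample_id",
                             values_to = "dosage")
  df <- inner_join(as_tibble(activity), dos, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$dosage), y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "dosage", y = "module activity (PC1)") +
    ggplot2::theme_classic()
}

#' @export
autoplot.orca_stat <- function(object, ...) {
  df <- as_tibble(object)
  df2 <- bind_rows(df, rename(df, seg_i = "seg_j", seg_j = "seg_i"))
  lab <- attr(object, "stat") %||% "value"
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$seg_i, y = .data$seg_j,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "segment", y = "segment", fill = lab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vcm_allele_scan <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$z_ref, y = .data$z_alt)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "max Z (REF)", y = "max Z (ALT)") +
    ggplot2::theme_classic()
}

#' Binned Capture-C interaction histogram
#'
#' @param profiles list of binned `vcm_capc` profiles (e.g. both genotypes).
#' @return a ggplot.
#' @export
plot_capturec <- function(profiles) {
  df <- purrr::map(profiles, function(p) {
    mutate(as_tibble(p), genotype = attr(p, "genotype"),
           replicate = attr(p, "replicate"))
  }) |> list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2e6,
                                   y = .data$norm_count,
                                   fill = .data$genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "position (Mb)", y = "TAD-normalised counts") +
    ggplot2::theme_classic()
}

#' TF-binding density track
#'
#' @param density output of [tf_binding_density()].
#' @return a ggplot.
#' @export
plot_tf_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(x = .data$start, y = .data$n_assays)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (bp)", y = "assays with a peak") +
    ggplot2::theme_classic()
}
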