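# ggplot2 views of envelope grids and speciation states.

#' @importFrom ggplot2 autoplot ggplot aes geom_ribbon geom_line geom_point
#'   labs theme_minimal
NULL

#' Plot a production envelope in the yield plane
#'
#' Reproduces the familiar envelope layout: biomass yield on x, product
#' yield on y, one band per bicarbonate ratio, with fermentation endpoints
#' optionally overlaid.
#'
#' @param object An `envelope_grid` from [compute_envelope()].
#' @param strains Optional strain endpoint table (columns as in
#'   [overlay_strains()]) to overlay as points; endpoints without a DCW or
#'   OD600 measurement are skipped.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.envelope_grid <- function(object, strains = NULL, ...) {
  mw <- attr(object, "mw")
  spec <- attr(object, "spec")
  uptake <- abs(spec$glucose_uptake)
  df <- as_tibble(object) |>
    dplyr::filter(.data$feasible) |>
    dplyr::mutate(
      ratio_label = factor(ifelse(is.infinite(.data$ratio), "unbounded",
                                  format(.data$ratio)),
                           levels = unique(ifelse(
                             is.infinite(sort(unique(.data$ratio))),
                             "unbounded",
                             format(sort(unique(.data$ratio)))))),
      yield_min = .data$product_min * mw[["product"]] /
        (uptake * mw[["glucose"]])
    )
  p <- ggplot(df, aes(x = .data$yield_biomass)) +
    geom_ribbon(aes(ymin = .data$yield_min, ymax = .data$yield_product,
                    fill = .data$ratio_label), alpha = 0.35) +
    geom_line(aes(y = .data$yield_product, colour = .data$ratio_label)) +
    labs(x = "biomass yield (g DCW/g glucose)",
         y = "3-HP yield (g/g glucose)",
         fill = "HCO3-:glucose", colour = "HCO3-:glucose") +
    theme_minimal()
  if (!is.null(strains)) {
    s <- as_tibble(strains)
    dcw <- if ("dcw" %in% names(s)) s$dcw else od_to_dcw(s$od600)
    s <- dplyr::mutate(s, yield_product = .data$titre / .data$glucose,
                       yield_biomass = dcw / .data$glucose)
    # endpoints without a biomass measurement cannot be placed on the plane
    s <- dplyr::filter(s, !is.na(.data$yield_biomass))
    p <- p + geom_point(data = s, aes(x = .data$yield_biomass,
                                      y = .data$yield_product)) +
      ggplot2::geom_text(data = s,
                         aes(x = .data$yield_biomass,
                             y = .data$yield_product,
                             label = .data$strain),
                         vjust = -0.6, size = 2.8)
  }
  p
}

#' Plot carbonate speciation fractions across pH
#'
#' @param pka1,pka2 Apparent pKa values.
#' @param ph_range pH interval to sweep.
#' @return A ggplot object.
#' @export
plot_speciation <- function(pka1 = 6.06, pka2 = 10.33,
                            ph_range = c(4, 12)) {
  ph <- seq(ph_range[1], ph_range[2], length.out = 200)
  df <- species_fractions(ph, pka1, pka2) |>
    tidyr::pivot_longer(dplyr::starts_with("f_"),
                        names_to = "species", values_to = "fraction") |>
    dplyr::mutate(species = dplyr::recode(.data$species, f_co2 = "CO2(aq)",
                                          f_hco3 = "HCO3-", f_co3 = "CO3--"))
  ggplot(df, aes(.data$ph, .data$fraction, colour = .data$species)) +
    geom_line() +
    labs(x = "pH", y = "fraction of DIC", colour = NULL) +
    theme_minimal()
}
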