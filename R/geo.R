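#' Regional hypertension prevalence
#'
#' Per region: number of women and prevalence (percent, rounded to one
#' decimal, half away from zero) of the four hypertension measures —
#' SBP >= 140 mmHg, DBP >= 90 mmHg, either, and the self-reported ever-told
#' flag. Counts are kept alongside so regional totals reconcile exactly with
#' national ones.
#'
#' @param data Woman-level data frame with `region`, `sbp`, `dbp`,
#'   `ever_told`.
#' @return A data frame with columns `region`, `n_women`, `count_*` and
#'   `prevalence_*` for each of `sbp`, `dbp`, `combined`, `ever_told`.
#' @export
regional_prevalence <- function(data) {
  if (any(is.na(data$region))) stop("every record must carry a region")
  flags <- classify_hypertension(data$sbp, data$dbp)
  flags$ever_told <- as.integer(data$ever_told)
  regions <- unique(data$region)
  out <- lapply(regions, function(rg) {
    ix <- data$region == rg
    n <- sum(ix)
    cnt <- colSums(flags[ix, , drop = FALSE])
    data.frame(region = rg, n_women = n,
               count_sbp = cnt[["sbp_flag"]],
               count_dbp = cnt[["dbp_flag"]],
               count_combined = cnt[["combined_flag"]],
               count_ever_told = cnt[["ever_told"]],
               prevalence_sbp = round_half_away(100 * cnt[["sbp_flag"]] / n, 1),
               prevalence_dbp = round_half_away(100 * cnt[["dbp_flag"]] / n, 1),
               prevalence_combined =
                 round_half_away(100 * cnt[["combined_flag"]] / n, 1),
               prevalence_ever_told =
                 round_half_away(100 * cnt[["ever_told"]] / n, 1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$region), , drop = FALSE]
}

.norm_region <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Render a prevalence choropleth
#'
#' Shades each region's polygon by a prevalence column from
#' [regional_prevalence()] on a sequential colour scale, with a legend.
#' Regions are matched to GeoJSON features by normalized name (trimmed,
#' case-insensitive); any tabled region without a matching feature is an
#' error, never silently dropped. Output is deterministic given the inputs.
#'
#' @param prevalence_table Output of [regional_prevalence()].
#' @param geometry A `"geo_feature_collection"` (e.g. [region_geometry()] or
#'   [read_geojson()]).
#' @param measure One of `"sbp"`, `"dbp"`, `"combined"`, `"ever_told"`.
#' @param file Output path; extension selects the device (`.png`, `.svg`,
#'   `.pdf`).
#' @param bins `NULL` for a continuous scale, or a number of equal-interval
#'   bins (e.g. 5).
#' @return `file`, invisibly.
#' @export
render_choropleth <- function(prevalence_table, geometry,
                              measure = c("sbp", "dbp", "combined",
                                          "ever_told"),
                              file, bins = NULL) {
  measure <- match.arg(measure)
  col_name <- paste0("prevalence_", measure)
  stopifnot(col_name %in% names(prevalence_table))
  feat_names <- vapply(geometry$features,
                       function(ft) as.character(ft$properties$name),
                       character(1))
  idx <- match(.norm_region(prevalence_table$region), .norm_region(feat_names))
  if (anyNA(idx)) {
    stop("no geometry for region(s): ",
         paste(prevalence_table$region[is.na(idx)], collapse = ", "))
  }
  vals <- prevalence_table[[col_name]]
  pal <- grDevices::colorRampPalette(c("#FEE5D9", "#A50F15"))
  if (is.null(bins)) {
    rng <- range(vals)
    rel <- if (diff(rng) > 0) (vals - rng[1]) / diff(rng) else rep(0.5,
                                                                  length(vals))
    cols <- pal(101)[1 + round(100 * rel)]
    leg_vals <- round(seq(rng[1], rng[2], length.out = 5), 1)
    leg_cols <- pal(5)
  } else {
    brk <- seq(min(vals), max(vals), length.out = bins + 1)
    brk[1] <- brk[1] - 1e-9
    cut_ix <- cut(vals, brk, labels = FALSE)
    cols <- pal(bins)[cut_ix]
    leg_vals <- round(brk[-1], 1)
    leg_cols <- pal(bins)
  }

  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = 900, height = 700),
         svg = grDevices::svg(file, width = 9, height = 7),
         pdf = grDevices::pdf(file, width = 9, height = 7),
         stop("unsupported output format: ", ext))
  on.exit(grDevices::dev.off())

  rings <- lapply(geometry$features[idx],
                  function(ft) ft$geometry$coordinates[[1]])
  all_xy <- do.call(rbind, rings)
  graphics::plot.new()
  graphics::plot.window(xlim = range(all_xy[, 1]), ylim = range(all_xy[, 2]),
                        asp = 1)
  for (i in seq_along(rings)) {
    graphics::polygon(rings[[i]][, 1], rings[[i]][, 2], col = cols[i],
                      border = "grey30")
    graphics::text(mean(range(rings[[i]][, 1])),
                   mean(range(rings[[i]][, 2])),
                   labels = prevalence_table$region[i], cex = 0.7)
  }
  graphics::title(main = sprintf("Hypertension prevalence (%s), %%", measure))
  graphics::legend("topright", legend = leg_vals, fill = leg_cols,
                   title = "%", bty = "n")
  invisible(file)
}
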