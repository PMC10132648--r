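#' Simulate a household-clustered bivariate blood-pressure cohort
#'
#' Draws households with 1–3 eligible women, household- and woman-level
#' categorical covariates, a bivariate household random effect
#' `(h1, h2) ~ N(0, sigma_h)` shared by all women of a household, and a
#' bivariate woman residual `(e1, e2) ~ N(0, sigma_e)`, then sets
#' `sbp = intercept_sbp + x'beta_sbp + h1 + e1` (likewise for `dbp`). An
#' ever-told-hypertension flag is drawn as an independent Bernoulli. Identical
#' `(config, seed)` pairs reproduce identical tables.
#'
#' @param config A [default_sim_config()]-style `"sim_config"`.
#' @param seed Integer seed; defaults to `config$seed`. Required.
#' @return A data frame, one row per woman: `woman_id`, `household_id`,
#'   `region`, `sbp`, `dbp`, `ever_told`, then one column per covariate with
#'   the scheme's category labels.
#' @examples
#' cfg <- default_sim_config(n_households = 50)
#' head(simulate_population(cfg, seed = 1))
#' @export
simulate_population <- function(config = default_sim_config(),
                                seed = config$seed) {
  validate_sim_config(config)
  if (is.null(seed)) stop("a seed is required (explicit or via config$seed)")
  set.seed(as.integer(seed))

  H <- config$n_households
  size_values <- as.integer(names(config$household_size_probs))
  sizes <- size_values[sample.int(length(size_values), H, replace = TRUE,
                                  prob = config$household_size_probs)]
  region <- sample(config$region_names, H, replace = TRUE,
                   prob = config$region_probs)

  scheme <- config$scheme
  hh_cov <- lapply(scheme$household_level, function(f) {
    sample(scheme$factors[[f]], H, replace = TRUE,
           prob = config$covariate_marginals[[f]])
  })
  names(hh_cov) <- scheme$household_level
  h_eff <- rmvn(H, config$sigma_h)

  N <- sum(sizes)
  hh <- rep.int(seq_len(H), sizes)

  wm_cov <- lapply(scheme$woman_level, function(f) {
    sample(scheme$factors[[f]], N, replace = TRUE,
           prob = config$covariate_marginals[[f]])
  })
  names(wm_cov) <- scheme$woman_level
  eps <- rmvn(N, config$sigma_e)
  ever <- stats::rbinom(N, 1L, config$ever_told_prob)

  df <- data.frame(
    woman_id = sprintf("W%05d", seq_len(N)),
    household_id = sprintf("H%05d", hh),
    region = region[hh],
    stringsAsFactors = FALSE
  )
  for (f in names(scheme$factors)) {
    df[[f]] <- if (f %in% scheme$woman_level) wm_cov[[f]] else hh_cov[[f]][hh]
  }

  X <- build_design(df, scheme)
  stopifnot(identical(colnames(X)[-1], rownames(config$beta)))
  xb <- X[, -1, drop = FALSE] %*% config$beta
  df$sbp <- as.numeric(config$intercepts[["sbp"]] + xb[, 1] +
                         h_eff[hh, 1] + eps[, 1])
  df$dbp <- as.numeric(config$intercepts[["dbp"]] + xb[, 2] +
                         h_eff[hh, 2] + eps[, 2])
  df$ever_told <- ever

  df[, c("woman_id", "household_id", "region", "sbp", "dbp", "ever_told",
         names(scheme$factors))]
}

#' Toy region geometry as a GeoJSON feature collection
#'
#' One unit-square polygon per region, laid out on a deterministic grid, with
#' the region name in the `name` property. Stands in for administrative
#' boundary shapefiles so the mapping stage runs without external downloads.
#'
#' @param region_names Character vector of unique region names.
#' @return A list of class `"geo_feature_collection"` following the RFC 7946
#'   FeatureCollection structure.
#' @examples
#' gj <- region_geometry(c("A", "B", "C"))
#' length(gj$features)
#' @export
region_geometry <- function(region_names) {
  if (length(region_names) < 1) stop("at least one region name required")
  if (anyDuplicated(region_names)) stop("region names must be unique")
  k <- length(region_names)
  ncols <- ceiling(sqrt(k))
  features <- lapply(seq_len(k), function(i) {
    cx <- (i - 1) %% ncols
    cy <- (i - 1) %/% ncols
    ring <- matrix(c(cx,     cy,
                     cx + 1, cy,
                     cx + 1, cy + 1,
                     cx,     cy + 1,
                     cx,     cy), ncol = 2, byrow = TRUE)
    list(type = "Feature",
         properties = list(name = region_names[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  structure(list(type = "FeatureCollection", features = features),
            class = "geo_feature_collection")
}

#' Read / write GeoJSON
#'
#' Thin RFC 7946 (de)serialization via JSON; `read_geojson()` reconstructs
#' polygon rings as coordinate matrices.
#'
#' @param x A `"geo_feature_collection"` (or compatible list).
#' @param path File path.
#' @return `write_geojson()` returns `path` invisibly; `read_geojson()` a
#'   `"geo_feature_collection"`.
#' @export
write_geojson <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(y$type) || y$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection")
  }
  y$features <- lapply(y$features, function(ft) {
    if (ft$geometry$type == "Polygon") {
      ft$geometry$coordinates <- lapply(ft$geometry$coordinates, function(ring) {
        do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
      })
    }
    ft
  })
  structure(y, class = "geo_feature_collection")
}
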