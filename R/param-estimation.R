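# Mapping experimental configurations to model parameters, and literature-
# derived parameter ranges packaged as JSON fixtures.

#' Nondimensionalize an experimental configuration
#'
#' Maps a dimensional channel/swimmer configuration to the nondimensional
#' triple: `rho = r0/h`, `alpha = U0*eps/v0`, `kappa = K*r0*l` (with `beta`
#' derived). When only a body length is available, a tail-beat scale of
#' `r0 = 0.2*l` is a typical choice.
#'
#' @inheritParams model_params
#' @return a [nondim_params()] object.
#' @examples
#' # Mexican tetra: l = 8.3 cm in a 25 cm channel, r0 = 0.2 l
#' nondimensionalize(h = 25, U0 = 2, eps = 0.05, v0 = 10, r0 = 0.2 * 8.3,
#'                   l = 8.3, K = 0)$rho
#' @export
nondimensionalize <- function(h, U0, eps, v0, r0, l, K = 0) {
  p <- model_params(h = h, U0 = U0, eps = eps, v0 = v0, r0 = r0, l = l, K = K)
  as_nondim(p)
}

#' Feedback gain from rheotaxis threshold speeds
#'
#' The model predicts that the critical background speed for stable upstream
#' swimming scales as `Uc(lateral line ablated) / Uc(intact) = 1 + kappa`,
#' so the gain is estimated as the ratio of threshold speeds minus one.
#' Ratios below one (ablated fish outperforming intact ones) are clamped to
#' `kappa = 0` with a warning.
#'
#' @param Uc_ablated threshold speed with the lateral line ablated (`> 0`).
#' @param Uc_intact threshold speed with the lateral line intact (`> 0`).
#' @return the estimated gain `kappa >= 0`.
#' @examples
#' kappa_from_thresholds(3, 1) # 2
#' @export
kappa_from_thresholds <- function(Uc_ablated, Uc_intact) {
  stopifnot(is.numeric(Uc_ablated), is.numeric(Uc_intact))
  if (any(Uc_ablated <= 0) || any(Uc_intact <= 0)) {
    stop("threshold speeds must be positive", call. = FALSE)
  }
  k <- Uc_ablated / Uc_intact - 1
  if (any(k < 0)) {
    warning("threshold ratio below 1; clamping kappa to 0", call. = FALSE)
    k <- pmax(k, 0)
  }
  k
}

preset_path <- function() {
  system.file("extdata", "literature_presets.json", package = "rheodipole",
              mustWork = TRUE)
}

# normalize one JSON entry field to list(type, value/lower/upper) or NULL
parse_entry <- function(e) {
  if (is.null(e)) return(NULL)
  if (identical(e$type, "point")) {
    list(type = "point", value = e$value)
  } else if (identical(e$type, "interval")) {
    if (e$lower > e$upper) stop("interval with lower > upper in presets fixture",
                                call. = FALSE)
    list(type = "interval", lower = e$lower, upper = e$upper)
  } else {
    stop("unknown entry type in presets fixture: ", e$type, call. = FALSE)
  }
}

#' Literature-derived parameter presets
#'
#' The nine literature configurations shipped with the package, as read from
#' the JSON fixture `extdata/literature_presets.json`. Point estimates
#' (printed as "~" values in the source ranges) are stored with
#' `type = "point"`, ranges with `type = "interval"`, and unavailable
#' entries as `NULL` (never imputed). Presets whose `alpha` was estimated
#' from the swimming speed of intact fish carry `alpha_estimated = TRUE`.
#'
#' @param path path to a presets JSON file; defaults to the packaged fixture.
#' @return a list of `experiment_preset` objects, each with fields `label`,
#'   `note`, `rho`, `eps`, `alpha`, `kappa`, `beta`, `alpha_estimated`.
#' @export
table1_presets <- function(path = preset_path()) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(row) {
    structure(list(label = row$label,
                   note = row$note,
                   rho = parse_entry(row$rho),
                   eps = parse_entry(row$eps),
                   alpha = parse_entry(row$alpha),
                   kappa = parse_entry(row$kappa),
                   beta = parse_entry(row$beta),
                   alpha_estimated = isTRUE(row$alpha_estimated)),
              class = "experiment_preset")
  })
}

entry_bounds <- function(e) {
  if (is.null(e)) c(NA_real_, NA_real_)
  else if (e$type == "point") c(e$value, e$value)
  else c(e$lower, e$upper)
}

#' Recompute the beta interval implied by a preset
#'
#' Bounds of `beta = alpha*(1+kappa)/rho^2` over a preset's stated ranges of
#' `rho`, `alpha` and `kappa` (the upper bound uses the smallest `rho`).
#' Returns `c(NA, NA)` when `alpha` or `kappa` is unavailable.
#'
#' @param preset an `experiment_preset`.
#' @return numeric `c(lower, upper)`.
#' @export
preset_beta_bounds <- function(preset) {
  stopifnot(inherits(preset, "experiment_preset"))
  a <- entry_bounds(preset$alpha)
  k <- entry_bounds(preset$kappa)
  r <- entry_bounds(preset$rho)
  if (anyNA(c(a, k, r))) return(c(NA_real_, NA_real_))
  c(a[1L] * (1 + k[1L]) / r[2L]^2, a[2L] * (1 + k[2L]) / r[1L]^2)
}

#' Point nondimensional parameters from a preset
#'
#' Collapses a preset to a single [nondim_params()] value, taking point
#' entries as-is and interval midpoints otherwise. Errors when `alpha` is
#' unavailable; a missing `kappa` is taken as 0 only if `explicit_kappa` is
#' `FALSE`.
#'
#' @param preset an `experiment_preset` (or its label, looked up in the
#'   packaged fixture).
#' @param kappa_if_missing value to use when the preset has no `kappa`
#'   estimate; default `NA` (error).
#' @return a [nondim_params()] object.
#' @export
preset_nondim <- function(preset, kappa_if_missing = NA_real_) {
  if (is.character(preset)) {
    all <- table1_presets()
    hit <- Filter(function(p) identical(p$label, preset), all)
    if (length(hit) == 0L) {
      stop("unknown preset label: ", preset, "; available: ",
           paste(vapply(all, `[[`, character(1), "label"), collapse = ", "),
           call. = FALSE)
    }
    preset <- hit[[1L]]
  }
  stopifnot(inherits(preset, "experiment_preset"))
  mid <- function(e) if (e$type == "point") e$value else (e$lower + e$upper) / 2
  if (is.null(preset$alpha)) {
    stop(sprintf("preset '%s' has no alpha estimate; supply rho/alpha/kappa directly",
                 preset$label), call. = FALSE)
  }
  kap <- if (is.null(preset$kappa)) {
    if (is.na(kappa_if_missing)) {
      stop(sprintf("preset '%s' has no kappa estimate; pass kappa_if_missing",
                   preset$label), call. = FALSE)
    }
    kappa_if_missing
  } else mid(preset$kappa)
  nondim_params(rho = mid(preset$rho), alpha = mid(preset$alpha), kappa = kap)
}

#' @export
print.experiment_preset <- function(x, ...) {
  fmt <- function(e) {
    if (is.null(e)) "-"
    else if (e$type == "point") sprintf("~%g", e$value)
    else sprintf("[%g, %g]", e$lower, e$upper)
  }
  cat(sprintf("<experiment_preset> %s: rho %s, eps %s, alpha %s%s, kappa %s, beta %s\n",
              x$label, fmt(x$rho), fmt(x$eps), fmt(x$alpha),
              if (x$alpha_estimated) "*" else "", fmt(x$kappa), fmt(x$beta)))
  invisible(x)
}

#' Presets as a flat table
#'
#' @param presets list from [table1_presets()].
#' @return a data.frame with one row per preset and lower/upper columns for
#'   each parameter (lower == upper for point estimates).
#' @export
presets_table <- function(presets = table1_presets()) {
  rows <- lapply(presets, function(p) {
    b <- lapply(p[c("rho", "eps", "alpha", "kappa", "beta")], entry_bounds)
    data.frame(label = p$label,
               rho_lo = b$rho[1L], rho_hi = b$rho[2L],
               eps_lo = b$eps[1L], eps_hi = b$eps[2L],
               alpha_lo = b$alpha[1L], alpha_hi = b$alpha[2L],
               kappa_lo = b$kappa[1L], kappa_hi = b$kappa[2L],
               beta_lo = b$beta[1L], beta_hi = b$beta[2L],
               alpha_estimated = p$alpha_estimated,
               note = p$note)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
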