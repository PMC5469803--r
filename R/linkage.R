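# Per-formula Spearman screening of mass-peak intensities against optical
# parameters, with class/count/intensity-share summaries and van Krevelen
# tables.

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of mid-ranks (average ranks on ties).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return rho in [-1, 1]; NA with a warning if either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Critical Spearman coefficient from the t approximation
#'
#' r_crit = t_q / sqrt(t_q^2 + n - 2), with t_q the Student-t quantile at
#' the requested confidence (one- or two-sided) on n - 2 degrees of
#' freedom. At n = 29, 99 % one-sided this evaluates to 0.43 (2 d.p.).
#'
#' @param n Sample size (>= 4).
#' @param confidence Confidence level in (0.5, 1).
#' @param tails "one" (default) or "two".
#' @return Critical correlation magnitude in (0, 1).
#' @export
critical_r <- function(n, confidence = 0.99, tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(n >= 4, confidence > 0.5, confidence < 1)
  alpha <- 1 - confidence
  q <- if (tails == "one") 1 - alpha else 1 - alpha / 2
  tq <- stats::qt(q, df = n - 2)
  tq / sqrt(tq^2 + n - 2)
}

# column-wise mid-rank transform
rank_columns <- function(m) {
  apply(m, 2, rank, ties.method = "average")
}

#' Screen formulae against optical parameters
#'
#' Computes the Spearman correlation of every formula's relative intensity
#' across samples with every optical parameter, flags pairs beyond the
#' critical value (positive and negative separately), and summarises
#' flagged sets per parameter: counts, mean signal-intensity share,
#' intensity-weighted mean molecular weight, and the number of formulae
#' with no flag of the given sign across all parameters ("NC").
#'
#' @param assigned Long tibble of assigned peaks with columns `sample_id`,
#'   `formula`, `rel_intensity`, `exact_mass`, `class` (rows as from
#'   [assign_formulas()]; unassigned rows are dropped). Formulae absent
#'   from a sample are zero-filled.
#' @param optical Tibble with `sample_id` plus one column per optical
#'   parameter (all numeric columns are used unless `parameters` is given).
#' @param parameters Optional character vector of optical columns to use.
#' @param confidence Confidence level of the screen (default 0.99).
#' @param tails "one" (default, reproduces r_crit 0.43 at n = 29) or "two".
#' @param r_threshold Optional override of the critical value.
#' @param min_present Minimum number of samples a formula must be detected
#'   in (default 3); rarer formulae are excluded from screening.
#' @param share "mean" (default): intensity share = mean across samples of
#'   the summed relative intensity of the flagged set; "pooled": share of
#'   the pooled summed intensity.
#' @return An object of class `dom_screen`: list with `flags` (long tibble
#'   formula x parameter with rho and flag), `summary` (per parameter and
#'   sign), `class_summary` (per parameter, sign and compound class),
#'   `n_formulae`, `r_crit`, `n_samples`.
#' @export
screen_formulae <- function(assigned, optical, parameters = NULL,
                            confidence = 0.99, tails = c("one", "two"),
                            r_threshold = NULL, min_present = 3,
                            share = c("mean", "pooled")) {
  tails <- match.arg(tails)
  share <- match.arg(share)
  stopifnot(all(c("sample_id", "formula", "rel_intensity") %in%
                  names(assigned)),
            "sample_id" %in% names(optical))
  assigned <- assigned |>
    dplyr::filter(!is.na(.data$formula), !is.na(.data$rel_intensity))

  if (is.null(parameters)) {
    parameters <- names(optical)[vapply(optical, is.numeric, logical(1))]
    parameters <- setdiff(parameters, c("station", "depth_m", "longitude",
                                        "doc_umol", "d", "theta_c",
                                        "salinity"))
  }
  samples <- sort(unique(assigned$sample_id))
  missing_opt <- setdiff(samples, optical$sample_id)
  if (length(missing_opt)) {
    stop(sprintf("optical table lacks samples: %s",
                 paste(missing_opt, collapse = ", ")))
  }
  n <- length(samples)
  r_crit <- if (is.null(r_threshold)) {
    critical_r(n, confidence, tails)
  } else {
    r_threshold
  }

  # formulae x samples intensity matrix, zero-filled
  wide <- assigned |>
    dplyr::select("sample_id", "formula", "rel_intensity") |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = "rel_intensity", values_fill = 0,
                       values_fn = sum)
  X <- as.matrix(wide[samples])
  rownames(X) <- wide$formula
  present <- rowSums(X > 0)
  X <- X[present >= min_present, , drop = FALSE]

  opt <- optical[match(samples, optical$sample_id), parameters, drop = FALSE]
  Y <- as.matrix(opt)

  rho <- stats::cor(rank_columns(t(X)), rank_columns(Y))  # formulae x params

  flags <- tibble::as_tibble(as.data.frame.table(rho,
                                                 responseName = "rho",
                                                 stringsAsFactors = FALSE))
  names(flags)[1:2] <- c("formula", "parameter")
  flags <- flags |>
    dplyr::mutate(flag = dplyr::case_when(
      .data$rho > r_crit ~ "positive",
      .data$rho < -r_crit ~ "negative",
      TRUE ~ "none"))

  meta <- assigned |>
    dplyr::distinct(.data$formula, .keep_all = TRUE) |>
    dplyr::select(dplyr::any_of(c("formula", "exact_mass", "class", "cram",
                                  "c", "h", "n", "o", "s", "p")))

  # per-sample summed share of a set of formulae, averaged or pooled
  share_of <- function(fs) {
    if (!length(fs)) return(0)
    sub <- X[rownames(X) %in% fs, , drop = FALSE]
    if (share == "mean") 100 * mean(colSums(sub)) else
      100 * sum(sub) / sum(X)
  }
  mean_mw_of <- function(fs) {
    if (!length(fs)) return(NA_real_)
    sub <- X[rownames(X) %in% fs, , drop = FALSE]
    w <- rowSums(sub)
    mw <- meta$exact_mass[match(rownames(sub), meta$formula)]
    if (sum(w) == 0) mean(mw) else sum(w * mw) / sum(w)
  }

  summarise_sign <- function(sgn) {
    flags |>
      dplyr::filter(.data$flag == sgn) |>
      dplyr::group_by(.data$parameter) |>
      dplyr::summarise(fs = list(.data$formula), .groups = "drop") |>
      dplyr::right_join(tibble::tibble(parameter = parameters),
                        by = "parameter") |>
      dplyr::mutate(
        sign = sgn,
        n_formulae = vapply(.data$fs, length, integer(1)),
        intensity_share_pct = vapply(.data$fs,
                                     function(f) share_of(unlist(f)),
                                     numeric(1)),
        mean_mw = vapply(.data$fs, function(f) mean_mw_of(unlist(f)),
                         numeric(1))) |>
      dplyr::select(-"fs")
  }
  summary <- dplyr::bind_rows(summarise_sign("positive"),
                              summarise_sign("negative"))

  # NC: formulae with no flag of that sign for any parameter
  nc <- flags |>
    dplyr::group_by(.data$formula) |>
    dplyr::summarise(any_pos = any(.data$flag == "positive"),
                     any_neg = any(.data$flag == "negative"),
                     .groups = "drop")

  class_summary <- flags |>
    dplyr::filter(.data$flag != "none") |>
    dplyr::left_join(meta, by = "formula") |>
    dplyr::group_by(.data$parameter, .data$flag, .data$class) |>
    dplyr::summarise(n_formulae = dplyr::n(), .groups = "drop")

  structure(list(flags = flags,
                 summary = summary,
                 class_summary = class_summary,
                 meta = meta,
                 n_formulae = nrow(X),
                 n_samples = n,
                 r_crit = r_crit,
                 n_nc_positive = sum(!nc$any_pos),
                 n_nc_negative = sum(!nc$any_neg)),
            class = "dom_screen")
}

#' @export
print.dom_screen <- function(x, ...) {
  cat(sprintf(
    "<dom_screen> %d formulae x %d parameters, n = %d samples, |r| > %.3f\n",
    x$n_formulae, length(unique(x$flags$parameter)), x$n_samples, x$r_crit))
  cat(sprintf("  positively flagged >= once: %d; NC (positive): %d\n",
              x$n_formulae - x$n_nc_positive, x$n_nc_positive))
  invisible(x)
}

#' Tidy a screening result
#'
#' @param x A `dom_screen` object.
#' @param ... Unused.
#' @return The per-parameter summary tibble.
#' @exportS3Method generics::tidy
tidy.dom_screen <- function(x, ...) x$summary

#' Van Krevelen table of flagged formulae
#'
#' One row per (formula, parameter, sign) flag with H/C, O/C and molecular
#' weight, ready for plotting.
#'
#' @param screen A `dom_screen` object.
#' @return Tibble with columns `formula`, `parameter`, `sign`, `hc`, `oc`,
#'   `mw`, `class`.
#' @export
van_krevelen_table <- function(screen) {
  stopifnot(inherits(screen, "dom_screen"))
  meta <- screen$meta |>
    dplyr::mutate(hc = .data$h / .data$c, oc = .data$o / .data$c)
  screen$flags |>
    dplyr::filter(.data$flag != "none") |>
    dplyr::left_join(meta, by = "formula") |>
    dplyr::transmute(.data$formula, .data$parameter, sign = .data$flag,
                     .data$hc, .data$oc, mw = .data$exact_mass,
                     .data$class)
}

#' Van Krevelen diagram of flagged formulae
#'
#' @param screen A `dom_screen` object.
#' @param parameter Optical parameter to show.
#' @param sign "positive" or "negative".
#' @return A ggplot.
#' @export
plot_van_krevelen <- function(screen, parameter, sign = "positive") {
  vk <- van_krevelen_table(screen) |>
    dplyr::filter(.data$parameter == !!parameter, .data$sign == !!sign)
  ggplot2::ggplot(vk, ggplot2::aes(x = .data$oc, y = .data$hc,
                                   colour = .data$mw)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_viridis_c(name = "MW (Da)") +
    ggplot2::labs(x = "O/C", y = "H/C",
                  title = sprintf("Formulae %sly correlated with %s",
                                  sign, parameter)) +
    ggplot2::theme_minimal()
}
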