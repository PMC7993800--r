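#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Q-Q flat-harmonic fit
#'
#' @param x a `qq_fit` from [fit_qq_parameters()]
#' @param ... unused
#' @return one row per fitted parameter (`term`, `estimate`)
#' @method tidy qq_fit
#' @export
tidy.qq_fit <- function(x, ...) {
  tibble(term = c("x0", "sigma", "dm"),
         estimate = c(x$x0, x$sigma, x$dm))
}

#' @rdname tidy.qq_fit
#' @return for `glance`: a one-row fit summary
#' @method glance qq_fit
#' @export
glance.qq_fit <- function(x, ...) {
  tibble(x0 = x$x0, sigma = x$sigma, dm = x$dm, n = x$n)
}

#' Tidy a quality report
#'
#' @param x an `ab_quality_report`
#' @param ... unused
#' @return the underlying criterion table as a plain tibble
#' @method tidy ab_quality_report
#' @export
tidy.ab_quality_report <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.ab_quality_report
#' @method glance ab_quality_report
#' @export
glance.ab_quality_report <- function(x, ...) {
  tibble(pdb_id = x$pdb_id[1], n_criteria = nrow(x),
         n_failed = sum(!x$pass), pass = all(x$pass))
}

#' Tidy a template database
#'
#' @param x an `ab_template_db`
#' @param ... unused
#' @return the pools tibble
#' @method tidy ab_template_db
#' @export
tidy.ab_template_db <- function(x, ...) {
  as_tibble(x$pools)
}

#' @rdname tidy.ab_template_db
#' @method glance ab_template_db
#' @export
glance.ab_template_db <- function(x, ...) {
  tibble(n_entries = x$provenance$n_entries,
         n_accepted = x$provenance$n_accepted,
         n_rejected = nrow(x$provenance$rejections),
         n_pools = nrow(distinct(x$pools, .data$region, .data$length)))
}

#' Tidy a benchmark report
#'
#' @param x an `ab_benchmark`
#' @param ... unused
#' @return per-target per-region RMSD rows as a plain tibble
#' @method tidy ab_benchmark
#' @export
tidy.ab_benchmark <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.ab_benchmark
#' @method glance ab_benchmark
#' @export
glance.ab_benchmark <- function(x, ...) {
  tibble(n_targets = length(unique(x$target_id)),
         n_rows = nrow(x),
         n_failed = sum(!x$pass),
         mean_rmsd = mean(x$rmsd, na.rm = TRUE))
}
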