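# Broom-style summaries and plots for parsed datasets.

#' Tidy a parsed ISA dataset
#'
#' One row per (assay, sample, factor) with the factor level as its grouping
#' key — the long view of the experimental design across every assay.
#'
#' @param x An `isa_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `assay_filename`, `sample`, `factor`,
#'   `level`.
#' @export
tidy.isa_dataset <- function(x, ...) {
  rows <- purrr::imap(x$factor_assignments, function(fa, af) {
    ps <- fa$per_sample
    if (length(fa$factor_names) == 0) {
      return(tibble::tibble(assay_filename = character(),
                            sample = character(), factor = character(),
                            level = character()))
    }
    long <- tidyr::pivot_longer(ps, dplyr::all_of(fa$factor_names),
                                names_to = "factor", values_to = "level")
    dplyr::mutate(long, assay_filename = af, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' One-line summary of a parsed ISA dataset
#'
#' @param x An `isa_dataset`.
#' @param ... Unused.
#' @return A one-row tibble: `n_studies`, `n_assays`, `n_samples` (distinct,
#'   across assays), `n_factors` (distinct factor names), `n_treatments` and
#'   `n_groups` (summed over assays).
#' @export
glance.isa_dataset <- function(x, ...) {
  tibble::tibble(
    n_studies = length(x$studies),
    n_assays = length(x$assay_tables),
    n_samples = length(unique(unlist(purrr::map(x$samples, unique)))),
    n_factors = length(unique(unlist(
      purrr::map(x$factor_assignments, "factor_names")))),
    n_treatments = sum(purrr::map_int(x$treatments, nrow)),
    n_groups = sum(purrr::map_int(x$groups, nrow))
  )
}

#' Group sizes of every assay, as a tibble
#'
#' @param ds An `isa_dataset`.
#' @return A tibble with `assay_filename`, `treatment` (joined factor-level
#'   label), `n_samples`.
#' @export
group_sizes <- function(ds) {
  rows <- purrr::imap(ds$groups, function(grp, af) {
    fns <- setdiff(names(grp), c("samples", "n_samples"))
    label <- if (length(fns)) {
      do.call(paste, c(unname(as.list(grp[, fns, drop = FALSE])), sep = " / "))
    } else {
      rep("(no factors)", nrow(grp))
    }
    tibble::tibble(assay_filename = af, treatment = label,
                   n_samples = grp$n_samples)
  })
  dplyr::bind_rows(rows)
}

#' Plot the treatment-group structure of a dataset
#'
#' A bar chart of group sizes per treatment, faceted by assay — a quick
#' visual check that the derived design matches expectations (balance,
#' missing combinations).
#'
#' @param object An `isa_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isa_dataset <- function(object, ...) {
  gs <- group_sizes(object)
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$treatment, y = .data$n_samples)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$assay_filename), scales = "free_x") +
    ggplot2::labs(x = "treatment (factor-level combination)",
                  y = "samples per group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
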