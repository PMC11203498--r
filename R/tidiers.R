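# broom-style accessors and ggplot2 methods for fitted objects and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' @param x An `mg_fit` from [pretrain()] or [finetune()].
#' @param ... Unused.
#' @return The per-epoch history tibble (`stage`, `epoch`, `lr`, `phase`,
#'   `train_loss`, `val_loss`).
#' @method tidy mg_fit
#' @export
tidy.mg_fit <- function(x, ...) x$history

#' @rdname tidy.mg_fit
#' @method glance mg_fit
#' @export
glance.mg_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    epochs = max(x$history$epoch),
    final_train_loss = dplyr::last(stats::na.omit(x$history$train_loss)),
    best_val_loss = if (all(is.na(x$history$val_loss))) NA_real_
                    else min(x$history$val_loss, na.rm = TRUE)
  )
}

#' Tidy an evaluation report
#'
#' @param x An `mg_report` from [evaluate_generation()].
#' @param ... Unused.
#' @return Long tibble of metric names and values.
#' @method tidy mg_report
#' @export
tidy.mg_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(metric = "valid", value = x$valid),
    tibble::tibble(metric = names(x$unique_at),
                   value = as.numeric(x$unique_at)),
    tibble::tibble(metric = "novel", value = x$novel),
    tibble::tibble(metric = paste0("wasserstein_", names(x$wasserstein)),
                   value = as.numeric(x$wasserstein))
  )
}

#' @rdname tidy.mg_report
#' @method glance mg_report
#' @export
glance.mg_report <- function(x, ...) {
  tibble::tibble(n_generated = x$n_generated, valid = x$valid,
                 novel = x$novel)
}

#' Loss curves for a training run
#'
#' @param object An `mg_fit`.
#' @param ... Unused.
#' @return A ggplot: training (and validation, when present) loss by epoch,
#'   colored by schedule phase.
#' @method autoplot mg_fit
#' @export
autoplot.mg_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  h <- h[!is.na(h$loss), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$phase), size = 1) +
    ggplot2::labs(x = "epoch", y = "next-token cross-entropy",
                  title = paste0(object$kind, " loss")) +
    ggplot2::theme_minimal()
}

#' Good-range bar chart for an evaluation report
#'
#' @param object An `mg_report`.
#' @param ... Unused.
#' @return A ggplot of the percentage of generated molecules inside each
#'   good drug-like property range.
#' @method autoplot mg_report
#' @export
autoplot.mg_report <- function(object, ...) {
  gr <- object$good_ranges
  ggplot2::ggplot(gr, ggplot2::aes(x = .data$property,
                                   y = .data$percent_in_range)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "% molecules in good range") +
    ggplot2::theme_minimal()
}

#' Property distribution overlay for generated vs reference molecules
#'
#' @param generated,reference Profile tibbles from [property_profile()].
#' @param properties Which property columns to facet.
#' @return A ggplot with density overlays per property.
#' @export
plot_property_distributions <- function(generated, reference,
                                        properties = c("mw", "tpsa", "logp",
                                                       "qed")) {
  gen <- dplyr::mutate(generated[properties], set = "generated")
  ref <- dplyr::mutate(reference[properties], set = "reference")
  long <- tidyr::pivot_longer(dplyr::bind_rows(gen, ref),
                              dplyr::all_of(properties),
                              names_to = "property", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "density")
}
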