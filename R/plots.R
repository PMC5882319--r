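# ggplot2 visualizations for the result types

km_step_data <- function(fit, label) {
  tibble::tibble(
    time = c(0, fit$time),
    surv = c(1, fit$surv),
    group = label
  )
}

#' @export
autoplot.km_fit <- function(object, ...) {
  df <- km_step_data(object, "all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Recurrence-free survival") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by risk class
#'
#' @param object A `signature_eval` from [evaluate_cohort()].
#' @param ... Unused.
#' @return A ggplot with one survival step curve per risk class and the
#'   log-rank p-value in the subtitle.
#' @export
autoplot.signature_eval <- function(object, ...) {
  km <- object$class_survival$km
  df <- dplyr::bind_rows(purrr::imap(km, km_step_data))
  lr <- object$class_survival$logrank
  sub <- if (!is.null(lr)) sprintf("log-rank p = %.4g", lr$p.value) else NULL
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::scale_colour_manual(values = c("Favorable" = "#2166ac",
                                            "Non-favorable" = "#b2182b")) +
    ggplot2::labs(x = "Years", y = "Recurrence-free survival",
                  colour = "Risk class", subtitle = sub) +
    ggplot2::theme_minimal()
}

#' GA fitness trajectory
#'
#' @param object A `ga_result` from [ga_select()].
#' @param ... Unused.
#' @return A ggplot of best-so-far and population-mean concordance per
#'   generation.
#' @export
autoplot.ga_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("best_c", "mean_c"),
                            names_to = "series", values_to = "c_index")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$c_index,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(best_c = "black", mean_c = "grey60"),
                                 labels = c(best_c = "best so far",
                                            mean_c = "population mean")) +
    ggplot2::labs(x = "Generation", y = "Harrell C", colour = NULL) +
    ggplot2::theme_minimal()
}
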