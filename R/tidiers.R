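# broom-style tidiers and ggplot2 methods for the package's result types.

#' @rdname cross_validate
#' @param x A `fluid_cv` object.
#' @param ... Unused.
#' @export
tidy.fluid_cv <- function(x, ...) {
  relocate(x$folds, "replicate", "fold")
}

#' @rdname cross_validate
#' @export
glance.fluid_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  mutate(wide, architecture = x$architecture, scheme = x$scheme,
         k = x$k, repeats = x$repeats)
}

#' @rdname train_teacher
#' @param x A `fluid_model`.
#' @param ... Unused.
#' @export
glance.fluid_model <- function(x, ...) {
  tibble(
    architecture = x$architecture,
    variant = x$variant %||% NA_character_,
    member_id = x$member_id %||% NA_character_,
    n_train = length(x$train_ids),
    n_neg = unname(x$label_counts["n_neg"]),
    n_pos = unname(x$label_counts["n_pos"]),
    seed = x$seed
  )
}

#' @rdname build_federated_set
#' @param x A `fluid_federated_set`.
#' @param ... Unused.
#' @export
tidy.fluid_federated_set <- function(x, ...) x$records

#' @rdname build_federated_set
#' @export
glance.fluid_federated_set <- function(x, ...) {
  tibble(n_records = nrow(x$records), n_pos = x$n_pos, n_neg = x$n_neg,
         n_per_class = x$provenance$n_per_class,
         reliability_min = x$provenance$reliability_min,
         shortfall = x$provenance$shortfall,
         class_ratio = if (x$n_pos > 0) x$n_neg / x$n_pos else NA_real_)
}

#' Plot an applicability-domain trend table
#'
#' Coverage on the x axis against each performance metric, one panel per
#' metric, with variants labelled along the trend.
#'
#' @param trend Output of [ad_trend()].
#' @return A ggplot object.
#' @export
plot_ad_trend <- function(trend) {
  long <- tidyr::pivot_longer(
    select(trend, -"coverage_delta"),
    cols = c("sensitivity", "specificity", "balanced_accuracy", "mcc"),
    names_to = "metric", values_to = "value"
  )
  ggplot(long, aes(x = .data$ad_coverage, y = .data$value)) +
    geom_line(colour = "grey50") +
    geom_point(aes(colour = .data$variant), size = 2) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "fraction of test set in applicability domain",
         y = "metric value", colour = "variant") +
    theme_minimal()
}

#' @rdname chemspace_embed
#' @param object A `fluid_embedding`.
#' @param ... Unused.
#' @export
autoplot.fluid_embedding <- function(object, ...) {
  ggplot(object, aes(x = .data$dim1, y = .data$dim2, colour = .data$set)) +
    geom_point(alpha = 0.6, size = 0.8) +
    labs(x = "dimension 1", y = "dimension 2", colour = "data set",
         title = "joint chemical-space embedding") +
    theme_minimal()
}

#' @rdname cross_validate
#' @param object A `fluid_cv` object.
#' @export
autoplot.fluid_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds,
    cols = c("balanced_accuracy", "specificity", "sensitivity", "precision",
             "auc", "mcc"),
    names_to = "metric", values_to = "value"
  )
  ggplot(long, aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    labs(x = NULL, y = "per-fold value",
         title = sprintf("%s: %s %d-fold x %d repeats", object$architecture,
                         object$scheme, object$k, object$repeats)) +
    theme_minimal()
}
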