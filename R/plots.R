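#' @export
autoplot.gmm_fit <- function(object, ...) {
  bt <- object$bic_table
  df <- tidyr::pivot_longer(
    tibble::as_tibble(as.data.frame(unclass(bt)), rownames = "k"),
    -"k", names_to = "model", values_to = "bic")
  df$k <- as.integer(df$k)
  ggplot2::ggplot(df[!is.na(df$bic), ],
                  ggplot2::aes(x = .data$k, y = .data$bic,
                               colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "mixture components (k)", y = "BIC = 2 lnL - p ln n",
                  title = paste0("Model selection: k = ", object$k, " (",
                                 object$model, ")")) +
    ggplot2::theme_minimal()
}

#' Barcode heatmap of a connectivity matrix
#'
#' @param conn A [connectivity_matrix()] tibble.
#' @param order Optional neuron order (e.g., from a clustering).
#' @return A ggplot.
#' @export
plot_barcode <- function(conn, order = NULL) {
  df <- tidyr::pivot_longer(conn, -"neuron_id", names_to = "domain",
                            values_to = "overlap")
  lev <- order %||% unique(conn$neuron_id)
  df$neuron_id <- factor(df$neuron_id, levels = lev)
  df$domain <- factor(df$domain,
                      levels = setdiff(names(conn), "neuron_id"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$domain, y = .data$neuron_id,
                                   fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "overlap\n(voxels)") +
    ggplot2::labs(x = "dendritic domain", y = "neuron",
                  title = "Connectivity barcodes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.subtype_result <- function(object, what = c("affinity", "ch"),
                                    ...) {
  what <- match.arg(what)
  if (what == "ch") {
    return(
      ggplot2::ggplot(object$ch, ggplot2::aes(x = .data$k, y = .data$ch)) +
        ggplot2::geom_line() +
        ggplot2::geom_point() +
        ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
        ggplot2::labs(x = "clusters (k)", y = "Calinski-Harabasz index",
                      title = paste0("Selected k = ", object$k)) +
        ggplot2::theme_minimal())
  }
  ord <- names(sort(object$labels))
  a <- object$bundle$A[ord, ord]
  df <- tibble::tibble(
    i = factor(rep(ord, times = length(ord)), levels = ord),
    j = factor(rep(ord, each = length(ord)), levels = rev(ord)),
    affinity = as.vector(a))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$affinity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Spatially tuned connectivity affinity (cluster-ordered)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
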