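# ggplot2 figures for the package's result types (ggplot2 is suggested, not
# required; each function checks for it).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting; install it or use the raw data")
}

#' Energy-versus-RMSD trace for a trajectory analysis
#'
#' The classic two-axis view: RMSD from the native structure and the
#' one-state GNN energy per frame.
#'
#' @param analysis Output of [analyze_trajectory()].
#' @return A ggplot object.
#' @export
plot_energy_rmsd <- function(analysis) {
  need_ggplot()
  scale <- max(analysis$E_os) / max(max(analysis$rmsd_nm), 1e-9)
  ggplot2::ggplot(analysis, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rmsd_nm, colour = "RMSD")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$E_os / scale, colour = "E_os")) +
    ggplot2::scale_y_continuous(
      name = "RMSD (nm)",
      sec.axis = ggplot2::sec_axis(~ . * scale, name = "E_os (kJ/mol)")) +
    ggplot2::scale_colour_manual(NULL, values = c(RMSD = "firebrick", E_os = "black")) +
    ggplot2::labs(x = "frame") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of an evaluation report
#'
#' @param report An `eval_report` from [evaluate_confusion()].
#' @return A ggplot object.
#' @export
plot_confusion <- function(report) {
  need_ggplot()
  cm <- report$confusion
  df <- expand.grid(true = rownames(cm), predicted = colnames(cm),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(cm)
  df$true <- factor(df$true, levels = rev(SS8_CLASSES))
  df$predicted <- factor(df$predicted, levels = SS8_CLASSES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$value), "",
                                                   sprintf("%.2f", .data$value))),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey90", limits = c(0, 1)) +
    ggplot2::labs(x = "mean predicted likelihood", y = "true SS8 motif",
                  fill = "p") +
    ggplot2::theme_minimal()
}

#' Training-history curves
#'
#' @param history The `history` data.frame returned by [train()].
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  need_ggplot()
  df <- rbind(
    data.frame(epoch = history$epoch, value = history$train_loss, series = "train loss"),
    data.frame(epoch = history$epoch, value = history$val_loss, series = "val loss"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}
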