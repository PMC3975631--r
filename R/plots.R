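#' Three-set Venn diagram of candidate lists
#'
#' Draws three overlapping circles with the seven region counts from
#' [overlap_stats()] and the total list sizes in bold, base graphics only.
#'
#' @param lists Named list of three candidate id vectors.
#' @return Invisibly, the [overlap_stats()] result.
#' @export
plot_candidate_venn <- function(lists) {
  ov <- overlap_stats(lists)
  if (is.null(ov$venn)) stopf("Venn plot needs exactly three lists")
  cx <- c(0.38, 0.62, 0.5); cy <- c(0.62, 0.62, 0.38); r <- 0.25
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
  th <- seq(0, 2 * pi, length.out = 200)
  cols <- grDevices::adjustcolor(c("#1b9e77", "#d95f02", "#7570b3"), 0.3)
  for (i in 1:3)
    graphics::polygon(cx[i] + r * cos(th), cy[i] + r * sin(th),
                      col = cols[i], border = NA)
  v <- ov$venn
  graphics::text(c(0.26, 0.74, 0.5), c(0.68, 0.68, 0.26), v[1:3])
  graphics::text(c(0.5, 0.38, 0.62), c(0.7, 0.45, 0.45), v[4:6])
  graphics::text(0.5, 0.54, v[7])
  graphics::text(c(0.2, 0.8, 0.5), c(0.92, 0.92, 0.06),
                 sprintf("%s (%d)", names(lists), ov$sizes), font = 2)
  invisible(ov)
}

#' Scatter plot of one separating pair
#'
#' Plots the two features' log2(CPM + 1) values for the samples of one
#' comparison, reference vs target groups in different symbols.
#'
#' @inheritParams enumerate_separating_pairs
#' @param pair Character vector of two feature ids.
#' @return Invisibly, the plotted coordinate matrix.
#' @export
plot_pair_scatter <- function(cpm, pair, metadata, target) {
  stopifnot(length(pair) == 2)
  cs <- comparison_samples(metadata, target)
  sel <- c(cs$ref, cs$target)
  X <- t(log2(as.matrix(cpm)[pair, sel, drop = FALSE] + 1))
  grp <- rep(c("non_metastasized", target), c(length(cs$ref), length(cs$target)))
  graphics::plot(X, pch = ifelse(grp == "non_metastasized", 1, 19),
                 xlab = paste0("log2 CPM+1, ", pair[1]),
                 ylab = paste0("log2 CPM+1, ", pair[2]),
                 main = paste(target, "vs non-metastasized"))
  graphics::legend("topleft", legend = c("non_metastasized", target),
                   pch = c(1, 19), bty = "n")
  invisible(X)
}
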