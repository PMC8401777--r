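# Structure colouring and force-plot rendering (base graphics). Atom and
# bond weights are normalised by the maximum absolute weight of the MMP, so
# colour darkness is comparable within one depiction: warm for positive
# contributions, blue for negative, white for zero.

weight_colour <- function(w, wmax, warm = "#E65100", cool = "#1565C0") {
  if (wmax <= 0) return(rep("#FFFFFF", length(w)))
  frac <- pmin(1, abs(w) / wmax)
  out <- character(length(w))
  for (i in seq_along(w)) {
    base <- if (w[i] >= 0) warm else cool
    out[i] <- grDevices::adjustcolor(base, alpha.f = 0.15 + 0.85 * frac[i])
  }
  out
}

draw_fragment <- function(mol, atom_w, bond_w, wmax, main = "",
                          warm = "#E65100", cool = "#1565C0") {
  xr <- range(mol$atoms$x); yr <- range(mol$atoms$y)
  pad <- 0.8
  plot(NA, xlim = xr + c(-pad, pad), ylim = yr + c(-pad, pad),
       asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  bw <- bond_w[as.character(seq_len(nrow(mol$bonds)))]
  bw[is.na(bw)] <- 0
  bcol <- weight_colour(bw, wmax, warm, cool)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    graphics::segments(mol$atoms$x[a], mol$atoms$y[a],
                       mol$atoms$x[b], mol$atoms$y[b],
                       lwd = 6, col = bcol[k])
    graphics::segments(mol$atoms$x[a], mol$atoms$y[a],
                       mol$atoms$x[b], mol$atoms$y[b],
                       lwd = 1.2, col = "grey25",
                       lty = if (mol$bonds$order[k] > 1) 1 else 1)
  }
  aw <- atom_w[as.character(seq_len(nrow(mol$atoms)))]
  aw[is.na(aw)] <- 0
  acol <- weight_colour(aw, wmax, warm, cool)
  graphics::points(mol$atoms$x, mol$atoms$y, pch = 21, cex = 2.6,
                   bg = acol, col = "grey40")
  lab <- mol$atoms$elem
  lab[lab == "C"] <- ""
  graphics::text(mol$atoms$x, mol$atoms$y, lab, cex = 0.8, font = 2)
}

#' Plot an atom/bond contribution map
#'
#' Draws the core and the two substituents side by side with atoms and
#' bonds coloured by accumulated contribution weight: warm colours for
#' positive (cliff-favouring) weight, blue for negative, white for zero,
#' normalised by the largest absolute weight in the MMP.
#'
#' @param x an `atom_weights` object from [map_to_structure()].
#' @param warm,cool colours for positive / negative weights.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.atom_weights <- function(x, warm = "#E65100", cool = "#1565C0", ...) {
  if (is.null(x$frags))
    stop("abstract fingerprint: no structures to draw")
  wmax <- if (nrow(x$weights)) max(abs(x$weights$weight)) else 0
  op <- graphics::par(mfrow = c(1, 3), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  titles <- c(core = "core", sub_low = "substituent (low)",
              sub_high = "substituent (high)")
  for (role in c("core", "sub_low", "sub_high")) {
    mol <- parse_mol(x$frags[[role]])
    wr <- x$weights[x$weights$role == role, , drop = FALSE]
    atom_w <- stats::setNames(wr$weight[wr$kind == "atom"],
                              wr$index[wr$kind == "atom"])
    bond_w <- stats::setNames(wr$weight[wr$kind == "bond"],
                              wr$index[wr$kind == "bond"])
    draw_fragment(mol, atom_w, bond_w, wmax, main = titles[[role]],
                  warm = warm, cool = cool)
  }
  invisible(x)
}

#' @rdname plot.atom_weights
#' @export
plot.ac_explanation <- function(x, ...) {
  plot(map_to_structure(x), ...)
}

#' Force-plot of a Kernel SHAP explanation
#'
#' Horizontal bars of the largest Shapley values, positive in warm colour,
#' negative in blue; absent features (bits not set in the explained
#' instance) are hatched and labelled `0`.
#'
#' @param x a `shap_explanation`.
#' @param top number of features to show.
#' @param warm,cool bar colours.
#' @param ... unused.
#' @export
plot.shap_explanation <- function(x, top = 12, warm = "#E65100",
                                  cool = "#1565C0", ...) {
  fr <- utils::head(force_report(x), top)
  fr <- fr[rev(seq_len(nrow(fr))), , drop = FALSE]
  col <- ifelse(fr$phi >= 0, warm, cool)
  dens <- ifelse(fr$present == 1, NA, 25)
  graphics::barplot(fr$phi, horiz = TRUE, col = col, density = dens,
                    names.arg = sprintf("bit %d (%d)", fr$bit, fr$present),
                    las = 1, cex.names = 0.7,
                    xlab = "Shapley value",
                    main = sprintf("baseline %.3f, output %.3f",
                                   x$phi0, x$fx))
  graphics::abline(v = 0, col = "grey40")
  invisible(x)
}

#' Training decision values of a fitted activity-cliff SVM
#'
#' @param x an `ac_svm`.
#' @param ... unused.
#' @export
plot.ac_svm <- function(x, ...) {
  d <- predict(x, x$fps, type = "decision")
  cls <- factor(x$labels, levels = c("NON_AC", "AC"))
  graphics::stripchart(d ~ cls, vertical = TRUE, method = "jitter",
                       pch = 19, col = c("#1565C0", "#E65100"),
                       ylab = "decision value", main = "training decisions")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
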