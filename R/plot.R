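#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_tile geom_segment
#'   geom_col scale_x_continuous scale_y_continuous scale_fill_identity
#'   scale_color_identity scale_alpha_identity coord_fixed labs theme_minimal
#'   theme element_blank
#' @importFrom rlang .data
NULL

#' Draw a worm plot
#'
#' @param wormData output of [wormPlotData()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plotWorm <- function(wormData, title = "Worm plot") {
  ref <- attr(wormData, "reference")
  clusters <- attr(wormData, "clusters")
  ggplot(wormData, aes(x = .data$x, y = .data$y, color = .data$cluster_pair)) +
    geom_hline(yintercept = c(-ref, ref), linetype = "dashed", color = "grey40") +
    geom_hline(yintercept = 0, color = "grey80") +
    geom_point(size = 0.6, show.legend = FALSE) +
    scale_x_continuous(breaks = seq_along(clusters) - 0.5, labels = clusters) +
    labs(title = title, x = "lobe-pair cluster (edges sorted by t)",
         y = expression(-log[10](p) %.% sign(t) %.% s)) +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Draw one panel of a bi-modal comparison plot
#'
#' Renders either a marginal per-kind histogram or one structural x
#' functional 2D histogram from [bimodalPlotData()].
#'
#' @param bimodal output of [bimodalPlotData()].
#' @param panel name of a joint panel (e.g. `"DMCxfMT"`) or of a kind for
#'   a marginal panel (e.g. `"DMC"`).
#' @return a ggplot object.
#' @export
plotBimodal <- function(bimodal, panel) {
  if (panel %in% names(bimodal$joint)) {
    j <- bimodal$joint[[panel]]
    b <- j$bins
    xm <- (j$xbreaks[b$xbin] + j$xbreaks[b$xbin + 1L]) / 2
    ym <- (j$ybreaks[b$ybin] + j$ybreaks[b$ybin + 1L]) / 2
    df <- data.frame(x = xm, y = ym,
                     fill = grDevices::rgb(b$r, b$g, b$b), alpha = b$alpha)
    ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$fill,
                   alpha = .data$alpha)) +
      geom_tile() + scale_fill_identity() + scale_alpha_identity() +
      labs(title = panel, x = j$structural, y = j$functional) +
      theme_minimal()
  } else if (panel %in% names(bimodal$marginal)) {
    m <- bimodal$marginal[[panel]]
    if (bimodal$mode == "group_means") {
      df <- rbind(
        data.frame(mid = m$mid, count = m$count0, fill = "red"),
        data.frame(mid = m$mid, count = m$count1, fill = "blue"))
      ggplot(df, aes(x = .data$mid, y = .data$count, fill = .data$fill)) +
        geom_col(position = "identity", alpha = 0.5, width = diff(m$lo[1:2])) +
        scale_fill_identity() + labs(title = panel, x = "weight", y = "edges") +
        theme_minimal()
    } else {
      ggplot(m, aes(x = .data$mid, y = .data$count)) +
        geom_col(fill = "darkgreen", width = diff(m$lo[1:2])) +
        labs(title = panel, x = "t", y = "edges") + theme_minimal()
    }
  } else stop("unknown panel: ", panel)
}

#' Draw a connectogram
#'
#' Straight chords between rim nodes; node points are colored by cluster
#' with saturation scaled by significant-edge degree.
#'
#' @param cg output of [connectogramData()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plotConnectogram <- function(cg, title = "Connectogram") {
  nodes <- cg$nodes
  th <- nodes$angle_deg * pi / 180
  nodes$px <- cos(th); nodes$py <- sin(th)
  clusters <- unique(nodes$cluster)
  base <- grDevices::hcl(h = seq(15, 375, length.out = length(clusters) + 1L)[seq_along(clusters)],
                         c = 100, l = 55)
  ci <- match(nodes$cluster, clusters)
  hsv0 <- grDevices::rgb2hsv(grDevices::col2rgb(base[ci]))
  nodes$col <- grDevices::hsv(hsv0[1, ], hsv0[2, ] * nodes$saturation, hsv0[3, ])
  p <- ggplot(nodes, aes(x = .data$px, y = .data$py))
  if (nrow(cg$edges)) {
    e <- cg$edges
    ia <- match(e$region_a, nodes$region_id)
    ib <- match(e$region_b, nodes$region_id)
    seg <- data.frame(x = nodes$px[ia], y = nodes$py[ia],
                      xend = nodes$px[ib], yend = nodes$py[ib],
                      color = e$color, alpha = e$opacity)
    p <- p + geom_segment(data = seg,
                          aes(x = .data$x, y = .data$y, xend = .data$xend,
                              yend = .data$yend, color = .data$color,
                              alpha = .data$alpha),
                          inherit.aes = FALSE) +
      scale_color_identity() + scale_alpha_identity()
  }
  p + geom_point(aes(color = .data$col), size = 2) +
    scale_color_identity() + coord_fixed() +
    labs(title = title) + theme_minimal() +
    theme(axis.title = element_blank(), axis.text = element_blank(),
          panel.grid = element_blank())
}

#' Draw a matrix heat map
#'
#' @param m output of [matrixPlotData()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plotMatrix <- function(m, title = "Matrix view") {
  r <- nrow(m)
  df <- expand.grid(row = seq_len(r), col = seq_len(r))
  df$value <- m[cbind(df$row, df$col)]
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile() +
    ggplot2::scale_fill_gradient2(na.value = "grey85") +
    ggplot2::scale_y_reverse() + coord_fixed() +
    labs(title = title, x = NULL, y = NULL, fill = "value") +
    theme_minimal()
}
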