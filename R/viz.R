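#' Plot a vessel network
#'
#' Draws the network on the generator's layout embedding (columns at
#' integer x, compartments stacked in y, the extranidal trees to either
#' side). Optionally highlights a filled vessel set.
#'
#' @param network a `trensh_network`.
#' @param filled optional `trensh_filled` or character vector of vessel ids
#'   drawn in blue.
#' @param main plot title.
#' @param lwd_fistula line width for the fistula.
#' @return invisibly, NULL.
#' @export
plot_network <- function(network, filled = NULL, main = NULL,
                         lwd_fistula = 2.5) {
  if (inherits(filled, "trensh_filled")) filled <- filled$vessels
  nd <- network$nodes
  v <- network$vessels
  xi <- nd$x[match(v$tail, nd$id)]
  yi <- nd$y[match(v$tail, nd$id)]
  xj <- nd$x[match(v$head, nd$id)]
  yj <- nd$y[match(v$head, nd$id)]
  intra <- v$category %in% INTRANIDAL_CATEGORIES
  col <- ifelse(v$id %in% filled, "#2166ac",
                ifelse(v$category %in% c("extranidal-artery", "AF"), "#d6604d",
                       ifelse(v$category %in% c("extranidal-vein", "DV"),
                              "#92c5de", "grey70")))
  lwd <- ifelse(v$category == "intranidal-fistula", lwd_fistula,
                ifelse(intra, 0.5, 1.5))
  graphics::plot(NA, xlim = range(c(xi, xj)), ylim = range(c(yi, yj)),
                 xlab = "layout x (nidus columns)", ylab = "layout y",
                 main = main, axes = FALSE)
  graphics::axis(1); graphics::axis(2)
  graphics::segments(xi, yi, xj, yj, col = col, lwd = lwd)
  term <- nd$role %in% c("AF-terminal", "DV-terminal")
  graphics::points(nd$x[term], nd$y[term], pch = 19, cex = 0.8)
  graphics::text(nd$x[term], nd$y[term], nd$id[term], pos = 2, cex = 0.7)
  invisible(NULL)
}

#' Render animation frames to PNG files
#'
#' One PNG per frame, filled vessels in blue over the network layout.
#' Optional stitching to MP4 is attempted with an external `ffmpeg` if one
#' is on the PATH; otherwise the PNG sequence is the deliverable.
#'
#' @param frames result of [animation_frames()].
#' @param network the network the frames describe.
#' @param out_dir output directory (created if needed).
#' @param stitch attempt MP4 stitching with ffmpeg.
#' @param width,height device size in pixels.
#' @return character vector of written file paths.
#' @export
render_animation <- function(frames, network, out_dir, stitch = FALSE,
                             width = 800, height = 500) {
  if (!length(frames)) stop("parameter error: empty frame list", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    paths[i] <- file.path(out_dir, sprintf("frame_%04d.png", i))
    grDevices::png(paths[i], width = width, height = height)
    plot_network(network, filled = f$vessels,
                 main = sprintf("%s | injection %d mmHg | %d vessels filled",
                                f$phase, f$injection_mmHg, length(f$vessels)))
    grDevices::dev.off()
  }
  if (stitch) {
    ffmpeg <- Sys.which("ffmpeg")
    if (nzchar(ffmpeg)) {
      out <- file.path(out_dir, "animation.mp4")
      system2(ffmpeg, c("-y", "-framerate", "5", "-i",
                        file.path(out_dir, "frame_%04d.png"),
                        "-pix_fmt", "yuv420p", out),
              stdout = FALSE, stderr = FALSE)
      if (file.exists(out)) paths <- c(paths, out)
    } else {
      warning("ffmpeg not found; PNG sequence written without MP4")
    }
  }
  paths
}
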