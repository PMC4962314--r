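# Hierarchical clustering of the enrichment matrix and the locus x tissue
# heatmap (Euclidean distance on the -ln q entries, average linkage).

#' Pairwise Euclidean distances between matrix rows or columns
#'
#' @param m numeric matrix (typically from [build_matrix()]).
#' @param axis `"rows"` or `"cols"`.
#' @return symmetric labelled distance matrix with zero diagonal.
#' @export
euclidean_distances <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  .chk(all(is.finite(m)), "matrix entries must be finite")
  if (axis == "cols") m <- t(m)
  if (nrow(m) < 2L) {
    warning("fewer than 2 ", axis, ": degenerate distance matrix",
            call. = FALSE)
  }
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' At each step the pair of clusters with the smallest average
#' inter-cluster distance is merged. Delegates to
#' `stats::hclust(method = "average")`.
#'
#' @param d symmetric distance matrix (e.g. from [euclidean_distances()]).
#' @return an `hclust` object (merge tree, heights, leaf order).
#' @export
average_linkage <- function(d) {
  d <- as.matrix(d)
  .chk(isSymmetric(unname(d)), "distance matrix must be symmetric")
  .chk(all(diag(d) == 0), "distance matrix must have a zero diagonal")
  if (nrow(d) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Export a dendrogram as Newick text
#'
#' @param tree `hclust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

# Reorder a matrix by the leaf orders of row/column dendrograms; exported
# for render tests (reorder invariance is a property of this step).
#' Reorder a matrix by dendrogram leaf order
#'
#' @param m matrix; `row_tree`, `col_tree`: `hclust` objects whose labels
#'   match the dimnames of `m` (either may be `NULL` to keep the axis
#'   order).
#' @param row_tree,col_tree `hclust` objects or `NULL`.
#' @return the reordered matrix.
#' @export
reorder_by_trees <- function(m, row_tree = NULL, col_tree = NULL) {
  if (!is.null(row_tree)) {
    .chk(setequal(row_tree$labels, rownames(m)),
         "row tree labels do not match matrix rownames")
    m <- m[row_tree$labels[row_tree$order], , drop = FALSE]
  }
  if (!is.null(col_tree)) {
    .chk(setequal(col_tree$labels, colnames(m)),
         "column tree labels do not match matrix colnames")
    m <- m[, col_tree$labels[col_tree$order], drop = FALSE]
  }
  m
}

#' Render the enrichment heatmap
#'
#' Draws the cell-type x locus matrix with both axes ordered by dendrogram
#' leaf order and a white-to-red colour ramp (white = not significant, deep
#' red = highly significant). Output device is chosen from the file
#' extension (`.png` or `.pdf`).
#'
#' @param m enrichment matrix.
#' @param row_tree,col_tree `hclust` objects from [average_linkage()], or
#'   `NULL` to leave an axis unordered.
#' @param path output image path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(m, row_tree = NULL, col_tree = NULL, path,
                           main = "risk-SNP enrichment (-ln q)") {
  m <- reorder_by_trees(m, row_tree, col_tree)
  ext <- tolower(tools::file_ext(path))
  .chk(ext %in% c("png", "pdf"), "unsupported image extension: .", ext)
  if (ext == "png") {
    grDevices::png(path, width = 1200, height = 900, res = 120)
  } else {
    grDevices::pdf(path, width = 10, height = 7.5)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  pal <- grDevices::colorRampPalette(c("white", "red"))(100)
  zmax <- max(m, na.rm = TRUE)
  if (zmax <= 0) zmax <- 1   # all-zero matrix renders uniform white
  graphics::par(mar = c(7, 8, 3, 2))   # private device, closed on exit
  # image() draws rows of its input along x; transpose so matrix rows =
  # heatmap rows, and flip so the first row is at the top
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = c(0, zmax), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.7, tick = FALSE)
  graphics::box()
  invisible(path)
}
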