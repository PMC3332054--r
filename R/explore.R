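#' Unsupervised hierarchical clustering of samples
#'
#' Clusters samples on the filtered log2-ratio matrix, cuts the tree into `k`
#' groups and tests each cluster for enrichment in each sample-group label by
#' one-sided Fisher exact test. Default distance is 1 - Pearson correlation
#' across probes with Ward linkage (`ward.D2`): on weakly correlated profiles,
#' single/average linkage spends the top of the tree isolating outlier samples
#' one by one, whereas Ward merges yield balanced clusters that track group
#' structure. A constant matrix (correlation undefined) falls back to
#' Euclidean distance with a warning.
#'
#' @param lr a [Log2RatioExperiment-class] with >= 2 samples.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage agglomeration method passed to [stats::hclust()] (default
#'   `"ward.D2"`; `"average"` and the other hclust methods are accepted).
#' @param k number of clusters to cut (default 4, mirroring the four major
#'   transcriptional subgroups expected under this study design).
#' @return a [ClusteringResult-class].
#' @export
clusterSamples <- function(lr, distance = c("correlation", "euclidean"),
                           linkage = "ward.D2", k = 4) {
  stopifnot(is(lr, "Log2RatioExperiment"))
  distance <- match.arg(distance)
  m <- log2Ratios(lr)
  if (ncol(m) < 2) stop("need >= 2 samples to cluster")
  if (distance == "correlation" && any(apply(m, 2, stats::sd) == 0)) {
    warning("constant sample profile: correlation undefined, ",
            "falling back to Euclidean distance")
    distance <- "euclidean"
  }
  d <- if (distance == "correlation") stats::as.dist(1 - stats::cor(m))
       else stats::dist(t(m))
  hc <- stats::hclust(d, method = linkage)
  k <- min(k, ncol(m))
  assign <- stats::cutree(hc, k = k)
  groups <- tryCatch(sampleGroups(lr), error = function(e) NULL)
  enr <- data.frame(cluster = integer(), group = character(),
                    overlap = integer(), cluster_size = integer(),
                    group_size = integer(), p = numeric())
  if (!is.null(groups)) {
    rows <- list()
    for (cl in sort(unique(assign))) {
      for (g in unique(groups)) {
        a <- sum(assign == cl & groups == g)
        b <- sum(assign == cl & groups != g)
        cc <- sum(assign != cl & groups == g)
        dd <- sum(assign != cl & groups != g)
        p <- stats::fisher.test(matrix(c(a, b, cc, dd), 2),
                                alternative = "greater")$p.value
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, group = g, overlap = a,
          cluster_size = a + b, group_size = a + cc, p = p,
          stringsAsFactors = FALSE)
      }
    }
    enr <- do.call(rbind, rows)
  }
  new("ClusteringResult", tree = hc, assignments = assign, k = as.integer(k),
      enrichment = enr, distance = distance, linkage = linkage)
}

#' Export the sample dendrogram in newick format
#'
#' @param result a [ClusteringResult-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeNewick <- function(result, path) {
  stopifnot(is(result, "ClusteringResult"))
  ape::write.tree(ape::as.phylo(result@tree), file = path)
  invisible(path)
}

#' Export a signature heatmap and the plotted values
#'
#' Renders a log2-ratio heatmap with rows grouped in signature blocks and
#' columns ordered control, PTPN11, SOS1, SHOC2, on a diverging palette
#' centered at 0. The plotted matrix is written alongside as TSV.
#'
#' @param lr a [Log2RatioExperiment-class].
#' @param signatures non-empty list of [Signature-class] objects; block order
#'   follows the list.
#' @param file image path (extension selects the device, e.g. `.png`).
#' @param tsv path of the companion TSV (default: `file` with `.tsv`).
#' @return invisibly, the plotted matrix.
#' @export
exportHeatmap <- function(lr, signatures, file,
                          tsv = paste0(tools::file_path_sans_ext(file), ".tsv")) {
  stopifnot(is(lr, "Log2RatioExperiment"))
  if (!length(signatures)) stop("empty signature list")
  stopifnot(all(vapply(signatures, is, TRUE, "Signature")))
  m <- log2Ratios(lr)
  probes <- unlist(lapply(signatures, probeIds), use.names = FALSE)
  if (!length(probes)) stop("signatures contain no probes")
  missing <- setdiff(probes, rownames(m))
  if (length(missing))
    stop("signature probes absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  groups <- sampleGroups(lr)
  colOrder <- order(match(groups, .GROUPS))
  mat <- m[probes, colOrder, drop = FALSE]
  sizes <- vapply(signatures, length, 1L)
  out <- data.frame(probe_id = probes,
                    signature = rep(vapply(signatures, function(s) s@comparison,
                                           character(1)), sizes),
                    as.data.frame(mat), check.names = FALSE)
  data.table::fwrite(out, tsv, sep = "\t")
  lim <- max(abs(mat), 1e-6)
  rownames(mat) <- make.unique(rownames(mat))
  colTab <- table(factor(groups, levels = .GROUPS))
  colTab <- colTab[colTab > 0]
  pheatmap::pheatmap(
    mat, cluster_rows = FALSE, cluster_cols = FALSE,
    gaps_row = cumsum(sizes)[-length(sizes)],
    gaps_col = cumsum(colTab)[-length(colTab)],
    breaks = seq(-lim, lim, length.out = 101),
    color = grDevices::colorRampPalette(c("green3", "black", "red"))(100),
    show_rownames = nrow(mat) <= 60, filename = file, silent = TRUE)
  invisible(mat)
}
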