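#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene ids; duplicates within
#'   a set are removed.
#' @param name collection name.
#' @param universe gene universe; defaults to the union of all sets. Sets are
#'   clipped to the universe.
#' @return a [GeneSetCollection-class].
#' @export
geneSetCollection <- function(sets, name = "collection", universe = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, intersect, universe)
  empty <- vapply(sets, length, 1L) == 0
  if (any(empty)) sets <- sets[!empty]
  if (!length(sets)) stop("no non-empty sets after harmonization with universe")
  new("GeneSetCollection", name = name, sets = sets, universe = universe)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line — set name, description, then
#' tab-separated gene ids. Duplicate genes within a set are deduplicated; the
#' universe defaults to the union of all sets unless supplied.
#'
#' @param path GMT file.
#' @param name collection name (defaults to the file name).
#' @param universe optional gene universe.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path, name = basename(path), universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d (%d fields, need >= 3)", i, length(f)))
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  geneSetCollection(sets, name = name, universe = universe)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output file.
#' @param descriptions optional per-set description column (default "na").
#' @return invisibly, the path.
#' @export
writeGMT <- function(collection, path, descriptions = NULL) {
  sets <- geneSets(collection)
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the actual overlap between the signature genes and the set, given the
#' universe. The signature is intersected with the universe before testing.
#'
#' @param genes character vector of signature gene ids.
#' @param collection a [GeneSetCollection-class].
#' @param maxP report only sets with p below this cutoff (default 1 = all).
#' @return data.frame with columns `set_name`, `overlap`, `set_size`,
#'   `signature_size`, `universe_size`, `p`, sorted by ascending p.
#' @examples
#' gsc <- geneSetCollection(list(A = letters[1:5]), universe = letters[1:20])
#' hypergeomEnrich(c("a", "b", "c", "f"), gsc)  # p ~ 0.03199
#' @export
hypergeomEnrich <- function(genes, collection, maxP = 1) {
  stopifnot(is(collection, "GeneSetCollection"))
  universe <- geneUniverse(collection)
  genes <- unique(genes)
  genes <- intersect(genes, universe)
  if (!length(genes))
    stop("no signature genes found in the collection universe; ",
         "harmonize gene identifiers first")
  N <- length(universe)
  n <- length(genes)
  sets <- geneSets(collection)
  res <- data.frame(
    set_name = names(sets),
    overlap = vapply(sets, function(s) length(intersect(genes, s)), 1L),
    set_size = vapply(sets, length, 1L),
    signature_size = n,
    universe_size = N,
    stringsAsFactors = FALSE, row.names = NULL)
  res$p <- stats::phyper(res$overlap - 1, res$set_size, N - res$set_size, n,
                         lower.tail = FALSE)
  if (maxP < 1) res <- res[res$p < maxP, , drop = FALSE]
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Direction-stratified over-representation of a signature
#'
#' Runs [hypergeomEnrich()] on all signature genes, or only on the up- or
#' downregulated subset.
#'
#' @param signature a [Signature-class] (probe ids are used as gene ids under
#'   a 1:1 probe-to-gene map).
#' @param collection a [GeneSetCollection-class].
#' @param direction `"both"`, `"up"` or `"down"`.
#' @param maxP p-value cutoff for reporting.
#' @return data.frame as in [hypergeomEnrich()].
#' @export
enrichSignature <- function(signature, collection,
                            direction = c("both", "up", "down"), maxP = 1) {
  stopifnot(is(signature, "Signature"))
  direction <- match.arg(direction)
  e <- signatureEntries(signature)
  if (direction != "both") e <- e[e$direction == direction, , drop = FALSE]
  hypergeomEnrich(e$probe_id, collection, maxP = maxP)
}

#' Detect transcription-factor/target circuits within a signature
#'
#' For every transcription factor (TF) that is itself in the signature and has
#' at least `minTargets` of its annotated targets also in the signature,
#' reports the TF's direction and per-probe t p-value, the split of target
#' directions, and an exact two-sided binomial test (p0 = 0.5) for directional
#' bias of the targets. A circuit is flagged when the TF is in the signature
#' and the target direction bias has p < 0.05; the orientation (targets
#' concordant or anti-correlated with the TF) is reported, not filtered.
#'
#' @param signature a [Signature-class].
#' @param tfTargets a [GeneSetCollection-class] whose set names are TF gene
#'   ids and members their predicted targets (same namespace as the signature).
#' @param minTargets minimum targets in the signature (default 3); TFs below
#'   it are skipped with a message.
#' @return data.frame with columns `tf`, `tf_direction`, `tf_p`,
#'   `n_targets_in_signature`, `n_targets_up`, `n_targets_down`,
#'   `n_targets_concordant`, `direction_bias_p`, `circuit`.
#' @export
circuitDetect <- function(signature, tfTargets, minTargets = 3) {
  stopifnot(is(signature, "Signature"), is(tfTargets, "GeneSetCollection"))
  e <- signatureEntries(signature)
  sets <- geneSets(tfTargets)
  tfs <- intersect(names(sets), e$probe_id)
  rows <- list()
  for (tf in tfs) {
    targets <- setdiff(sets[[tf]], tf)
    inSig <- intersect(targets, e$probe_id)
    if (length(inSig) < minTargets) {
      message(sprintf("TF %s skipped: only %d of its targets in signature (< %d)",
                      tf, length(inSig), minTargets))
      next
    }
    tfRow <- e[e$probe_id == tf, ]
    dirs <- e$direction[match(inSig, e$probe_id)]
    nUp <- sum(dirs == "up")
    nDown <- sum(dirs == "down")
    biasP <- stats::binom.test(nUp, nUp + nDown, p = 0.5)$p.value
    rows[[tf]] <- data.frame(
      tf = tf, tf_direction = tfRow$direction, tf_p = tfRow$t_p,
      n_targets_in_signature = length(inSig),
      n_targets_up = nUp, n_targets_down = nDown,
      n_targets_concordant = if (tfRow$direction == "up") nUp else nDown,
      direction_bias_p = biasP,
      circuit = biasP < 0.05,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(tf = character(), tf_direction = character(),
                      tf_p = numeric(), n_targets_in_signature = integer(),
                      n_targets_up = integer(), n_targets_down = integer(),
                      n_targets_concordant = integer(),
                      direction_bias_p = numeric(), circuit = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$direction_bias_p), , drop = FALSE]
}
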