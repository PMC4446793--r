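#' Scoring scheme for local-alignment marker detection
#'
#' Conventional protein-search defaults: BLOSUM62 with affine gap penalties
#' of 11 (open) and 1 (extend).
#'
#' @param matrix_name name of a substitution matrix shipped with
#'   Biostrings (e.g. `"BLOSUM62"`), or an actual scoring matrix.
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return list of class `"detection_scoring"`.
#' @export
detection_scoring <- function(matrix_name = "BLOSUM62", gap_open = 11,
                              gap_extend = 1) {
  if (is.character(matrix_name)) {
    e <- new.env()
    utils::data(list = matrix_name, package = "Biostrings", envir = e)
    mat <- get(matrix_name, envir = e)
  } else mat <- as.matrix(matrix_name)
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend),
            class = "detection_scoring")
}

#' Smith-Waterman local alignment score with affine gaps
#'
#' @param query,target non-empty protein sequences (character scalars).
#' @param scoring a [detection_scoring()].
#' @return the optimal local alignment score (`>= 0`; 0 when no positive
#'   scoring local alignment exists).
#' @export
local_align_score <- function(query, target, scoring = detection_scoring()) {
  if (!nzchar(query) || !nzchar(target)) stop("empty sequence")
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = TRUE)
  max(0, as.numeric(s))
}

#' Presence/undetected matrix of taxa by markers
#'
#' The stored state is "undetected", never "absent": failure to detect a
#' marker in a (possibly partial) sequence set is weak evidence of genomic
#' loss.
#'
#' @param states character matrix taxa x markers with entries `"present"`
#'   or `"undetected"`.
#' @param scores optional numeric matrix of best local-alignment scores
#'   (same shape, `>= 0`).
#' @return object of class `"presence_absence_matrix"`.
#' @export
presence_absence_matrix <- function(states, scores = NULL) {
  states <- as.matrix(states)
  if (!all(states %in% c("present", "undetected")))
    stop("states must be 'present' or 'undetected'")
  if (is.null(rownames(states)) || is.null(colnames(states)))
    stop("states must carry taxon rownames and marker colnames")
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    stopifnot(identical(dim(scores), dim(states)),
              all(scores >= 0, na.rm = TRUE))
  }
  structure(list(states = states, scores = scores),
            class = "presence_absence_matrix")
}

#' @export
print.presence_absence_matrix <- function(x, ...) {
  cat(sprintf("presence/absence: %d taxa x %d markers, %d undetected cells\n",
              nrow(x$states), ncol(x$states), sum(x$states == "undetected")))
  invisible(x)
}

# identity-based score threshold for one reference sequence: the score a
# local alignment of `span` residues at `pid` identity would achieve under
# the reference's residue composition
identity_threshold <- function(ref, scoring, pid = 0.35, span = 60L) {
  sm <- scoring$matrix
  aa <- intersect(rownames(sm), AA_ALPHABET)
  comp <- table(factor(strsplit(ref, "")[[1]], levels = aa))
  f <- as.numeric(comp) / max(1, sum(comp))
  e_diag <- sum(f * diag(sm[aa, aa]))
  off <- outer(f, f) * sm[aa, aa]; diag(off) <- 0
  denom <- 1 - sum(f^2)
  e_off <- if (denom > 0) sum(off) / denom else 0
  span <- min(span, nchar(ref))
  max(0, span * (pid * e_diag + (1 - pid) * e_off))
}

#' Detect marker genes in per-taxon sequence sets
#'
#' A cell is "present" iff the best local-alignment score of any reference
#' of the marker against any sequence of the taxon reaches the marker's
#' threshold. The default threshold policy is the score an alignment of
#' 35% identity over 60 residues (or the reference length, if shorter)
#' would achieve under the scoring matrix and the reference's residue
#' composition; a fixed numeric threshold may be given instead.
#'
#' @param sequence_sets named list: taxon -> character vector of protein
#'   sequences (may be empty: all markers "undetected" with a warning,
#'   since transcriptome absence is not genomic loss).
#' @param markers named list: marker -> character vector of reference
#'   protein sequences (at least one each).
#' @param threshold either `"identity"` (default policy) or a single
#'   number used for every marker.
#' @param scoring a [detection_scoring()].
#' @return a [presence_absence_matrix()] with best scores.
#' @export
detect_presence <- function(sequence_sets, markers, threshold = "identity",
                            scoring = detection_scoring()) {
  if (any(!vapply(markers, length, integer(1))))
    stopifnot(all(vapply(markers, length, integer(1)) >= 1L))
  taxa <- names(sequence_sets)
  mk <- names(markers)
  if (is.null(taxa) || is.null(mk)) stop("sequence_sets and markers must be named")
  thr <- vapply(markers, function(refs) {
    if (identical(threshold, "identity"))
      min(vapply(refs, identity_threshold, numeric(1), scoring = scoring))
    else as.numeric(threshold)
  }, numeric(1))
  st <- matrix("undetected", length(taxa), length(mk),
               dimnames = list(taxa, mk))
  sc <- matrix(0, length(taxa), length(mk), dimnames = list(taxa, mk))
  for (tx in taxa) {
    seqs <- sequence_sets[[tx]]
    if (length(seqs) == 0L) {
      warning("empty sequence set for taxon ", tx,
              ": markers recorded as undetected")
      next
    }
    subject <- Biostrings::AAStringSet(seqs)
    for (m in mk) {
      best <- 0
      for (ref in markers[[m]]) {
        s <- Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(rep(ref, length(subject))), subject,
          type = "local", substitutionMatrix = scoring$matrix,
          gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
          scoreOnly = TRUE)
        best <- max(best, s)
      }
      sc[tx, m] <- max(0, best)
      if (sc[tx, m] >= thr[m]) st[tx, m] <- "present"
    }
  }
  presence_absence_matrix(st, sc)
}

#' Map marker losses on a rooted tree by Dollo parsimony
#'
#' Each marker is gained once, at the most recent common ancestor of the
#' taxa where it is present, and lost on the minimal set of branches
#' explaining the undetected taxa below that ancestor: the loss branches
#' are the stems of the maximal all-undetected subtrees within the
#' ancestor's clade (provably minimal under single-gain-then-losses).
#' Undetected taxa outside the ancestor's clade simply never gained the
#' marker.
#'
#' @param tree rooted `ape::phylo` spanning the matrix taxa.
#' @param matrix a [presence_absence_matrix()].
#' @return object of class `"dollo_reconstruction"`: per marker, `losses`
#'   (branch ids = labels of the nodes below the loss branches),
#'   `n_losses`, and `never_detected` (no present taxon at all).
#' @export
dollo_map <- function(tree, matrix) {
  stopifnot(inherits(matrix, "presence_absence_matrix"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  taxa <- rownames(matrix$states)
  if (!setequal(taxa, tree$tip.label))
    stop("tree does not span the matrix taxa")
  tree <- ensure_node_labels(tree)
  nt <- length(tree$tip.label)
  nnodes <- nt + tree$Nnode
  node_label <- c(tree$tip.label, tree$node.label)
  po <- stats::reorder(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  markers <- colnames(matrix$states)
  losses <- setNames(vector("list", length(markers)), markers)
  never <- setNames(logical(length(markers)), markers)
  for (m in markers) {
    undet <- setNames(matrix$states[, m] == "undetected", taxa)
    present_tips <- which(!undet[tree$tip.label])
    if (length(present_tips) == 0L) {
      losses[[m]] <- character(0); never[m] <- TRUE; next
    }
    origin <- if (length(present_tips) == 1L) present_tips[[1]]
              else ape::getMRCA(tree, present_tips)
    # all-undetected flag per node, postorder
    allu <- logical(nnodes)
    allu[seq_len(nt)] <- undet[tree$tip.label]
    for (e in seq_len(nrow(po$edge))) {
      par <- po$edge[e, 1]
      allu[par] <- all(vapply(kids[[as.character(par)]],
                              function(k) allu[k], logical(1)))
    }
    # nodes within the origin clade
    inside <- logical(nnodes); inside[origin] <- TRUE
    for (e in rev(seq_len(nrow(po$edge))))     # preorder
      if (inside[po$edge[e, 1]]) inside[po$edge[e, 2]] <- TRUE
    loss_nodes <- integer(0)
    for (e in seq_len(nrow(po$edge))) {
      chd <- po$edge[e, 2]; par <- po$edge[e, 1]
      if (inside[chd] && allu[chd] && !allu[par])
        loss_nodes <- c(loss_nodes, chd)
    }
    losses[[m]] <- node_label[loss_nodes]
  }
  structure(list(losses = losses,
                 n_losses = vapply(losses, length, integer(1)),
                 never_detected = never),
            class = "dollo_reconstruction")
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  for (m in names(x$losses))
    cat(sprintf("%s: %s\n", m,
                if (x$never_detected[m]) "never detected"
                else paste0(x$n_losses[m], " loss(es)",
                            if (x$n_losses[m]) paste0(" on ",
                              paste(x$losses[[m]], collapse = ", ")) else "")))
  invisible(x)
}
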