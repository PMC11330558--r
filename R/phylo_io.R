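#' Read a set of time-calibrated trees
#'
#' Reads one or more rooted, branch-length-bearing trees from a Newick or
#' NEXUS file (NEXUS translate tables are resolved). Every tree is validated:
#' exactly one root, strictly positive branch lengths, unique tip labels.
#'
#' @param path Path to a tree file.
#' @param format `"auto"` (default, by extension/content), `"newick"` or
#'   `"nexus"`.
#' @param mcc Optional path to a separate maximum-clade-credibility tree kept
#'   alongside the posterior set.
#' @return A `multiPhylo` object; if `mcc` was supplied the designated tree is
#'   attached as `attr(trees, "mcc")`.
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus"), mcc = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop("failed to parse ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(trees)) stop("failed to parse ", format, " file '", path, "'")
  if (inherits(trees, "phylo")) {
    trees <- structure(list(trees), class = "multiPhylo")
  }
  for (i in seq_along(trees)) validate_phylogeny(trees[[i]])
  if (!is.null(mcc)) {
    mcc_tree <- read_trees(mcc, format = format)[[1]]
    attr(trees, "mcc") <- mcc_tree
  }
  trees
}

#' Write trees to Newick
#'
#' Branch lengths are written with 15 significant digits so that a
#' write/read round trip preserves them to near machine precision.
#'
#' @param trees A `phylo` or `multiPhylo`.
#' @param path Output file path.
#' @export
write_trees <- function(trees, path) {
  ape::write.tree(trees, file = path, digits = 15)
  invisible(path)
}

#' Validate a time-calibrated phylogeny
#'
#' Checks the invariants every downstream computation relies on: a single
#' root, branch lengths present and strictly positive, and unique tip labels.
#' Zero-length branches are rejected rather than jittered; pass
#' `jitter_zero = TRUE` to replace exact zeros with `eps` Myr instead.
#'
#' @param tree A `phylo` object.
#' @param jitter_zero Replace zero-length branches by `eps` instead of
#'   erroring.
#' @param eps Jitter length in Myr used when `jitter_zero = TRUE`.
#' @return The (possibly jittered) tree, invisibly validated.
#' @export
validate_phylogeny <- function(tree, jitter_zero = FALSE, eps = 1e-8) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dups, collapse = ", "))
  }
  n <- ape::Ntip(tree)
  # exactly one root: one node that never appears as a child
  children <- tree$edge[, 2]
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, children)
  if (length(roots) != 1L) stop("tree must have exactly one root (found ",
                                length(roots), ")")
  bad <- which(tree$edge.length < 0)
  if (length(bad)) {
    stop("negative branch length on edge(s): ",
         paste(apply(tree$edge[bad, , drop = FALSE], 1, paste, collapse = "->"),
               collapse = ", "))
  }
  zero <- which(tree$edge.length == 0)
  if (length(zero)) {
    if (jitter_zero) {
      tree$edge.length[zero] <- eps
    } else {
      stop("zero-length branch on edge(s): ",
           paste(apply(tree$edge[zero, , drop = FALSE], 1, paste, collapse = "->"),
                 collapse = ", "),
           " (set jitter_zero = TRUE to replace by eps)")
    }
  }
  invisible(tree)
}

#' Root-to-node depths (time since the root, Myr)
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over all nodes (tips first, then internal nodes,
#'   in ape's numbering).
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Node ages in Ma before present
#'
#' The youngest tip anchors age 0 unless an explicit `root_age_ma` places the
#' tree on an absolute timescale (required whenever environmental curves are
#' involved).
#'
#' @param tree A `phylo` object.
#' @param root_age_ma Optional absolute root age (Ma).
#' @return Numeric vector of ages (Ma) over all nodes.
#' @export
node_ages <- function(tree, root_age_ma = NULL) {
  d <- node_depths(tree)
  if (is.null(root_age_ma)) {
    root_age_ma <- max(d[seq_len(ape::Ntip(tree))])
  }
  root_age_ma - d
}

#' Prune a tree to a set of taxa
#'
#' Keeps exactly the named tips, suppressing unary nodes and summing their
#' branch lengths, so all pairwise path lengths among kept taxa are
#' preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to keep (at least 2).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(keep) < 2) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, keep)
}

#' Brownian-motion covariance (shared path length) matrix
#'
#' Entry (i, j) is the root-to-MRCA path length shared by tips i and j; the
#' diagonal holds root-to-tip path lengths, which differ among fossil tips.
#' Under Brownian motion with rate \eqn{\sigma^2} the trait covariance is
#' \eqn{\sigma^2} times this matrix.
#'
#' @param tree A `phylo` object.
#' @return A symmetric positive semi-definite matrix indexed by tip labels.
#' @export
bm_covariance <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Read a per-taxon trait table
#'
#' Expects CSV with columns `taxon`, `max_length_cm`, and optionally
#' `habitat`, `palaeolatitude_deg`, `clade`, `suborder`. `log_size` (natural
#' log of `max_length_cm`) is recomputed to guarantee the identity holds.
#'
#' @param path CSV path.
#' @return A data.frame with a `log_size` column.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("taxon", "max_length_cm")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("trait table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$taxon)) stop("duplicate taxa in trait table")
  if (any(!is.finite(tab$max_length_cm)) || any(tab$max_length_cm <= 0)) {
    stop("max_length_cm must be positive and finite")
  }
  tab$log_size <- log(tab$max_length_cm)
  if ("habitat" %in% names(tab)) {
    bad <- setdiff(unique(stats::na.omit(tab$habitat)), habitat_states())
    if (length(bad)) stop("unknown habitat state(s): ", paste(bad, collapse = ", "))
  }
  if ("palaeolatitude_deg" %in% names(tab)) {
    lat <- tab$palaeolatitude_deg
    if (any(abs(lat) > 90, na.rm = TRUE)) stop("palaeolatitude outside [-90, 90]")
  }
  tab
}

#' The fixed three-state habitat alphabet
#' @return Character vector `c("marine", "marginal", "continental")`.
#' @export
habitat_states <- function() c("marine", "marginal", "continental")

# Pairwise MRCA depth matrix among tips (equals bm_covariance) computed by
# brute-force path intersection; kept internal, used by regime machinery.
.mrca_depths <- function(tree) {
  full <- ape::mrca(tree, full = TRUE)
  d <- node_depths(tree)
  matrix(d[full], nrow = nrow(full))
}
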