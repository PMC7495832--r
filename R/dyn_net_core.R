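# Core containers: dynamic networks, static networks, homology tables,
# alignments.  Snapshots are undirected simple graphs stored as two-column
# character matrices of canonical edges (endpoint1 < endpoint2); a node is
# "present" in a snapshot iff it has at least one incident edge there.

#' Canonicalize an undirected edge list
#'
#' Orders each endpoint pair so that the lexicographically smaller node id
#' comes first, and drops duplicate rows. Self-loops are an error: snapshots
#' are simple graphs.
#'
#' @param a,b Character vectors of endpoint ids (recycled to equal length).
#' @return A two-column character matrix with columns `a` and `b`,
#'   one row per distinct undirected edge.
#' @keywords internal
canonical_edges <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (any(a == b)) {
    stop("self-loop edge(s) not allowed: ", paste(unique(a[a == b]), collapse = ", "))
  }
  lo <- ifelse(a < b, a, b)
  hi <- ifelse(a < b, b, a)
  m <- cbind(a = lo, b = hi)
  m[!duplicated(paste(lo, hi, sep = "\r")), , drop = FALSE]
}

edge_keys <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  paste(edges[, 1L], edges[, 2L], sep = "\r")
}

#' Construct a dynamic network from a list of snapshot edge sets
#'
#' A dynamic network is an ordered sequence of undirected simple-graph
#' snapshots over a shared node universe. Snapshot indices are implicit and
#' contiguous: the i-th list element is snapshot `i - 1` (0-based, matching
#' the on-disk format).
#'
#' @param snapshots A list; each element is a two-column matrix (or
#'   data.frame) of edges for one snapshot. Empty snapshots are allowed.
#' @return An object of class `dynamic_network` with elements `snapshots`
#'   (list of canonical edge matrices) and `nodes` (sorted character vector:
#'   every node incident to at least one edge in at least one snapshot).
#' @export
#' @examples
#' dn <- dynamic_network(list(
#'   rbind(c("a", "b")),
#'   rbind(c("a", "b"), c("b", "c"))
#' ))
#' n_snapshots(dn)
dynamic_network <- function(snapshots) {
  stopifnot(is.list(snapshots))
  snaps <- lapply(snapshots, function(e) {
    if (is.null(e) || (is.matrix(e) && nrow(e) == 0L) || length(e) == 0L) {
      return(matrix(character(0), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
    }
    if (is.data.frame(e)) e <- as.matrix(e)
    if (!is.matrix(e) || ncol(e) != 2L) stop("each snapshot must be a 2-column edge matrix")
    canonical_edges(e[, 1L], e[, 2L])
  })
  nodes <- sort(unique(unlist(lapply(snaps, as.character), use.names = FALSE)))
  structure(list(snapshots = snaps, nodes = nodes), class = "dynamic_network")
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat(sprintf(
    "<dynamic_network> %d snapshot(s), %d node(s), %s edges per snapshot\n",
    length(x$snapshots), length(x$nodes),
    paste(vapply(x$snapshots, nrow, 0L), collapse = "/")
  ))
  invisible(x)
}

#' Number of snapshots in a dynamic network
#' @param dn A `dynamic_network`.
#' @return Integer count of snapshots.
#' @export
n_snapshots <- function(dn) length(dn$snapshots)

#' Nodes present (incident to an edge) in one snapshot
#' @param dn A `dynamic_network`.
#' @param i 1-based snapshot position.
#' @return Sorted character vector of present nodes.
#' @export
snapshot_nodes <- function(dn, i) {
  sort(unique(as.character(dn$snapshots[[i]])))
}

#' Convert one snapshot to an igraph graph
#'
#' Convenience interop: the snapshot's simple undirected graph, with all
#' nodes of the dynamic network's universe as (possibly isolated) vertices.
#'
#' @param dn A `dynamic_network`.
#' @param i 1-based snapshot position.
#' @return An `igraph` graph.
#' @export
snapshot_igraph <- function(dn, i) {
  igraph::graph_from_edgelist(dn$snapshots[[i]], directed = FALSE) +
    igraph::vertices(setdiff(dn$nodes, snapshot_nodes(dn, i)))
}

#' Read a dynamic network from a timestamped edge-list file
#'
#' The format is one interaction per line: `node_a<TAB>node_b<TAB>snapshot`,
#' where `snapshot` is a 0-based integer index. Lines starting with `#` and
#' blank lines are ignored; any whitespace separates fields. Duplicate edges
#' within one snapshot are collapsed; self-loops are rejected. Snapshot
#' indices need not appear in order; indices missing below the maximum give
#' empty snapshots so that indices stay contiguous.
#'
#' @param path File path.
#' @return A `dynamic_network`.
#' @export
read_dynamic_network <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(dynamic_network(list()))
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d: expected 'node_a node_b snapshot_index'", idx[bad[1L]]))
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  t_chr <- vapply(parts, `[[`, "", 3L)
  t <- suppressWarnings(as.integer(t_chr))
  if (anyNA(t)) {
    stop(sprintf("malformed line %d: snapshot index '%s' is not an integer",
                 idx[which(is.na(t))[1L]], t_chr[which(is.na(t))[1L]]))
  }
  if (any(t < 0L)) {
    stop(sprintf("line %d: negative snapshot index %d", idx[which(t < 0L)[1L]], min(t)))
  }
  loops <- which(a == b)
  if (length(loops) > 0L) {
    stop(sprintf("line %d: self-loop edge (%s, %s)", idx[loops[1L]], a[loops[1L]], b[loops[1L]]))
  }
  n_snap <- max(t) + 1L
  snaps <- lapply(seq_len(n_snap) - 1L, function(k) {
    sel <- t == k
    if (!any(sel)) return(NULL)
    cbind(a[sel], b[sel])
  })
  dynamic_network(snaps)
}

#' Write a dynamic network to a timestamped edge-list file
#'
#' Inverse of [read_dynamic_network()]: `node_a<TAB>node_b<TAB>snapshot`,
#' snapshot indices 0-based.
#'
#' @param dn A `dynamic_network`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dynamic_network <- function(dn, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# node_a\tnode_b\tsnapshot", con)
  for (i in seq_along(dn$snapshots)) {
    e <- dn$snapshots[[i]]
    if (nrow(e) > 0L) {
      writeLines(paste(e[, 1L], e[, 2L], i - 1L, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Construct a static network
#'
#' @param edges Two-column matrix of undirected edges.
#' @param confidence Optional numeric vector of positive per-edge confidence
#'   weights, parallel to the rows of `edges`.
#' @param nodes Optional character vector of nodes; defaults to the edge
#'   endpoints.
#' @return An object of class `static_network` with canonical `edges`,
#'   `confidence` (possibly `NULL`, reordered with the edges) and `nodes`.
#' @export
static_network <- function(edges, confidence = NULL, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  canon <- canonical_edges(edges[, 1L], edges[, 2L])
  if (!is.null(confidence)) {
    if (length(confidence) != nrow(edges)) {
      stop("confidence must have one value per edge row")
    }
    if (any(confidence <= 0)) stop("confidence weights must be positive")
    # map original rows onto the deduplicated canonical rows (keep max)
    lo <- ifelse(edges[, 1L] < edges[, 2L], edges[, 1L], edges[, 2L])
    hi <- ifelse(edges[, 1L] < edges[, 2L], edges[, 2L], edges[, 1L])
    key <- paste(lo, hi, sep = "\r")
    conf <- tapply(confidence, key, max)
    confidence <- as.numeric(conf[edge_keys(canon)])
  }
  nodes <- sort(unique(c(as.character(canon), as.character(nodes))))
  structure(list(edges = canon, confidence = confidence, nodes = nodes),
            class = "static_network")
}

#' @export
print.static_network <- function(x, ...) {
  cat(sprintf("<static_network> %d node(s), %d edge(s)%s\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$confidence)) "" else ", weighted"))
  invisible(x)
}

#' Aggregate (flatten) a dynamic network into its static version
#'
#' A static edge exists between two nodes iff at least one snapshot contains
#' that edge; the node set is unchanged. This is the standard time-series
#' flattening used to contrast dynamic-aware and static alignment.
#'
#' @param x A `dynamic_network`.
#' @param ... Ignored.
#' @return A `static_network`.
#' @export
#' @method aggregate dynamic_network
aggregate.dynamic_network <- function(x, ...) {
  all_edges <- do.call(rbind, x$snapshots)
  static_network(all_edges, nodes = x$nodes)
}

#' Read a homology table in BLAST tabular layout
#'
#' Parses a whitespace/tab-separated BLAST tabular (`-outfmt 6`-like) file
#' and retains the candidate set of homolog pairs: rows with
#' e-value strictly below `evalue_max` (default 1e-7). When a pair occurs on
#' several rows (multiple HSPs), the row with the smallest e-value is kept.
#'
#' @param path File path.
#' @param evalue_max Strict upper bound on retained e-values.
#' @param evalue_col,bitscore_col 1-based column positions of the e-value and
#'   bit-score fields (defaults 11 and 12, the standard outfmt 6 layout).
#' @return An object of class `homology_table`: a data.frame with columns
#'   `query`, `subject`, `evalue`, `bitscore`.
#' @export
read_homology_table <- function(path, evalue_max = 1e-7,
                                evalue_col = 11L, bitscore_col = 12L) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(homology_table(character(0), character(0), numeric(0), numeric(0)))
  }
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  need <- max(evalue_col, bitscore_col)
  bad <- which(lengths(parts) < need)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d: fewer than %d columns", idx[bad[1L]], need))
  }
  q <- vapply(parts, `[[`, "", 1L)
  s <- vapply(parts, `[[`, "", 2L)
  ev_chr <- vapply(parts, `[[`, "", evalue_col)
  bs_chr <- vapply(parts, `[[`, "", bitscore_col)
  ev <- suppressWarnings(as.numeric(ev_chr))
  bs <- suppressWarnings(as.numeric(bs_chr))
  if (anyNA(ev)) {
    stop(sprintf("line %d: non-numeric e-value '%s'",
                 idx[which(is.na(ev))[1L]], ev_chr[which(is.na(ev))[1L]]))
  }
  if (anyNA(bs)) {
    stop(sprintf("line %d: non-numeric bit-score '%s'",
                 idx[which(is.na(bs))[1L]], bs_chr[which(is.na(bs))[1L]]))
  }
  sel <- ev < evalue_max
  q <- q[sel]; s <- s[sel]; ev <- ev[sel]; bs <- bs[sel]
  if (length(q) > 0L) {
    key <- paste(q, s, sep = "\r")
    ord <- order(ev)                       # smallest e-value first
    first <- ord[!duplicated(key[ord])]
    first <- sort(first)
    q <- q[first]; s <- s[first]; ev <- ev[first]; bs <- bs[first]
  }
  homology_table(q, s, ev, bs)
}

#' Construct a homology table from vectors
#'
#' @param query,subject Character vectors of protein ids (one per network).
#' @param evalue,bitscore Numeric vectors of BLAST statistics.
#' @return A `homology_table` data.frame.
#' @export
homology_table <- function(query, subject, evalue, bitscore) {
  df <- data.frame(query = as.character(query), subject = as.character(subject),
                   evalue = as.numeric(evalue), bitscore = as.numeric(bitscore),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(df$query, df$subject, sep = "\r"))) {
    stop("duplicate (query, subject) pairs in homology table")
  }
  class(df) <- c("homology_table", "data.frame")
  df
}

#' Construct an alignment object
#'
#' An alignment is a one-to-one mapping between nodes of two networks,
#' carried as a data.frame with the per-pair score components.
#'
#' @param node1,node2 Character vectors of matched node ids (parallel).
#' @param s_h,s_t Numeric vectors: sequence-based and time-warp similarity
#'   per matched pair.
#' @param alpha Weight used to combine the two components.
#' @return An object of class `alignment`: data.frame with columns `node1`,
#'   `node2`, `s_h`, `s_t`, `score`, with attributes `objective` (total
#'   score) and `alpha`.
#' @export
alignment <- function(node1, node2, s_h = numeric(length(node1)),
                      s_t = numeric(length(node1)), alpha = 0.5) {
  node1 <- as.character(node1); node2 <- as.character(node2)
  if (anyDuplicated(node1) || anyDuplicated(node2)) {
    stop("alignment is not one-to-one: a node appears in more than one pair")
  }
  score <- alpha * s_h + (1 - alpha) * s_t
  df <- data.frame(node1 = node1, node2 = node2, s_h = s_h, s_t = s_t,
                   score = score, stringsAsFactors = FALSE)
  attr(df, "objective") <- sum(score)
  attr(df, "alpha") <- alpha
  class(df) <- c("alignment", "data.frame")
  df
}

#' Total objective score of an alignment
#' @param aln An `alignment`.
#' @return The summed pair scores f(A).
#' @export
alignment_objective <- function(aln) attr(aln, "objective")

#' Write an alignment to a TSV file
#'
#' One matched pair per line (`node1<TAB>node2<TAB>s_h<TAB>s_t<TAB>score`),
#' preceded by a `#` header comment carrying the total objective score.
#'
#' @param aln An `alignment`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# objective_score=%.17g alpha=%.17g",
                     alignment_objective(aln), attr(aln, "alpha")), con)
  writeLines("# node1\tnode2\ts_h\ts_t\tpair_score", con)
  if (nrow(aln) > 0L) {
    writeLines(sprintf("%s\t%s\t%.17g\t%.17g\t%.17g",
                       aln$node1, aln$node2, aln$s_h, aln$s_t, aln$score), con)
  }
  invisible(path)
}

#' Read an alignment written by [write_alignment()]
#' @param path File path.
#' @return An `alignment`.
#' @export
read_alignment <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^# objective_score=", lines)]
  alpha <- 0.5
  if (length(hdr) == 1L) {
    alpha <- as.numeric(sub(".*alpha=([-0-9.eg+]+).*", "\\1", hdr))
  }
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(data_lines) == 0L) {
    return(alignment(character(0), character(0), numeric(0), numeric(0), alpha = alpha))
  }
  parts <- strsplit(data_lines, "\t")
  alignment(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L),
            s_h = as.numeric(vapply(parts, `[[`, "", 3L)),
            s_t = as.numeric(vapply(parts, `[[`, "", 4L)),
            alpha = alpha)
}
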