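#' Build a word-trajectory speech graph
#'
#' Maps a token sequence to a directed multigraph: one node per unique word
#' type, one directed edge for every pair of consecutive tokens *within* an
#' utterance. No edge is drawn across an utterance boundary (boundaries
#' encode interruptions). Immediate repetitions yield self-loops; repeated
#' transitions yield parallel edges, which are retained in the edge multiset
#' (component sizes do not depend on multiplicity, but other graph attributes
#' would).
#'
#' @param x an `sg_transcript`, a list of character vectors (one per
#'   utterance), or a single character vector (one utterance).
#' @return An object of class `speech_graph`: list with `nodes` (character
#'   vector of word types), `edges` (data.frame `from`, `to`; one row per
#'   edge instance) and `n_tokens`.
#' @examples
#' g <- speech_graph(list(c("a", "b"), c("c", "d")))
#' nrow(g$edges)  # 2: no edge spans the boundary
#' @export
speech_graph <- function(x) {
  utts <- if (inherits(x, "sg_transcript")) x$utterances
          else if (is.list(x)) lapply(x, as.character)
          else list(as.character(x))
  utts <- utts[vapply(utts, length, 0L) > 0L]
  toks <- unlist(utts, use.names = FALSE)
  if (!length(toks))
    sg_stop("empty graph: transcript has no tokens", "sgdem_empty_graph")
  nodes <- unique(toks)
  from <- to <- character(0)
  for (u in utts) {
    if (length(u) > 1L) {
      from <- c(from, u[-length(u)])
      to <- c(to, u[-1L])
    }
  }
  structure(
    list(nodes = nodes,
         edges = data.frame(from = from, to = to, stringsAsFactors = FALSE),
         n_tokens = length(toks)),
    class = "speech_graph")
}

#' @export
print.speech_graph <- function(x, ...) {
  cc <- connectedness(x)
  cat(sprintf("<speech_graph> %d nodes, %d edges (lcc=%d, lsc=%d)\n",
              length(x$nodes), nrow(x$edges), cc$lcc, cc$lsc))
  invisible(x)
}

# ---- component machinery (integer node ids 1..n) -------------------------

# Largest weakly connected component via union-find with path compression.
lcc_core <- function(from, to, n) {
  parent <- seq_len(n)
  find <- function(v) {
    r <- v
    while (parent[r] != r) r <- parent[r]
    while (parent[v] != r) { nxt <- parent[v]; parent[v] <<- r; v <- nxt }
    r
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, 0L)
  max(tabulate(roots, nbins = n))
}

# Largest strongly connected component, iterative Kosaraju. Singleton nodes
# are SCCs of size 1, so any non-empty graph has lsc >= 1.
lsc_core <- function(from, to, n) {
  adj <- lapply(split(to, factor(from, levels = seq_len(n))), as.integer)
  radj <- lapply(split(from, factor(to, levels = seq_len(n))), as.integer)
  visited <- logical(n)
  order <- integer(n); oi <- 0L
  for (s in seq_len(n)) {
    if (visited[s]) next
    visited[s] <- TRUE
    stack <- s; ptr <- 1L
    while (length(stack)) {
      d <- length(stack)
      v <- stack[d]; nb <- adj[[v]]; i <- ptr[d]
      pushed <- FALSE
      while (i <= length(nb)) {
        w <- nb[i]; i <- i + 1L
        if (!visited[w]) {
          visited[w] <- TRUE
          ptr[d] <- i
          stack <- c(stack, w); ptr <- c(ptr, 1L)
          pushed <- TRUE
          break
        }
      }
      if (!pushed) {
        oi <- oi + 1L; order[oi] <- v
        stack <- stack[-d]; ptr <- ptr[-d]
      }
    }
  }
  # second pass on the transposed graph, nodes in reverse finish order
  comp <- integer(n)
  best <- 0L
  for (s in rev(order)) {
    if (comp[s]) next
    size <- 0L
    queue <- s; comp[s] <- 1L
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      size <- size + 1L
      for (w in radj[[v]]) if (!comp[w]) { comp[w] <- 1L; queue <- c(queue, w) }
    }
    if (size > best) best <- size
  }
  best
}

# Both attributes from an integer token stream. `edge_ok[k]` says whether an
# edge connects stream positions k and k+1 (FALSE at utterance boundaries).
conn_from_stream <- function(ids, edge_ok) {
  loc <- match(ids, unique(ids))
  n <- max(loc)
  if (length(loc) > 1L) {
    from <- loc[-length(loc)][edge_ok]
    to <- loc[-1L][edge_ok]
  } else from <- to <- integer(0)
  list(lcc = lcc_core(from, to, n), lsc = lsc_core(from, to, n))
}

graph_int_edges <- function(g) {
  list(from = match(g$edges$from, g$nodes),
       to = match(g$edges$to, g$nodes),
       n = length(g$nodes))
}

#' Largest connected component (LCC)
#'
#' Node count of the largest component of the *undirected* version of the
#' graph: the largest set of word types in which every pair is linked by some
#' path, ignoring edge direction. Interpreted as the diversity of lexical
#' items woven into connected discourse.
#'
#' @param g a `speech_graph`.
#' @return integer, between 1 and the number of nodes.
#' @export
lcc <- function(g) {
  stopifnot(inherits(g, "speech_graph"))
  e <- graph_int_edges(g)
  lcc_core(e$from, e$to, e$n)
}

#' Largest strongly connected component (LSC)
#'
#' Node count of the largest set of word types that are *mutually* reachable
#' along directed paths (a reaches b and b reaches a). A single node is
#' trivially strongly connected, so the value is at least 1 for any non-empty
#' graph. The measure captures long-range recurrence in word sequencing and
#' is stricter than [lcc()].
#'
#' @param g a `speech_graph`.
#' @return integer, between 1 and [lcc()] of the same graph.
#' @export
lsc <- function(g) {
  stopifnot(inherits(g, "speech_graph"))
  e <- graph_int_edges(g)
  lsc_core(e$from, e$to, e$n)
}

#' Both connectedness attributes of a speech graph
#'
#' @param g a `speech_graph`.
#' @return list with integer elements `lcc` and `lsc`; `lsc <= lcc` always.
#' @export
connectedness <- function(g) {
  stopifnot(inherits(g, "speech_graph"))
  e <- graph_int_edges(g)
  list(lcc = lcc_core(e$from, e$to, e$n), lsc = lsc_core(e$from, e$to, e$n))
}

#' Export a speech graph
#'
#' `write_edgelist()` writes one `from<TAB>to` line per edge instance;
#' `write_graph_json()` writes `{"nodes": [...], "edges": [[from, to], ...]}`
#' for visualization tools.
#'
#' @param g a `speech_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "speech_graph"))
  writeLines(paste(g$edges$from, g$edges$to, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
write_graph_json <- function(g, path) {
  stopifnot(inherits(g, "speech_graph"))
  edges <- unname(Map(function(f, t) c(f, t), g$edges$from, g$edges$to))
  jsonlite::write_json(list(nodes = g$nodes, edges = edges), path)
  invisible(path)
}

#' @export
as.data.frame.speech_graph <- function(x, ...) x$edges
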