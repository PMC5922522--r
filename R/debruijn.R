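#' Build a de Bruijn graph from reads
#'
#' Nodes are (k-1)-mers, edges are the k-mers observed in the reads and
#' their reverse complements (both orientations are stored, so the graph of
#' a read and of its reverse complement is identical). Reads are split at
#' ambiguous bases (`N`) before k-merization and pieces shorter than `k` are
#' skipped. Edges observed fewer than `min_count` times are pruned — the
#' standard guard against sequencing-error k-mers, appropriate at moderate
#' depth; at very low depth (the ~4x regime) `min_count = 1` preserves
#' sensitivity and error paths are handled by tip/bubble clipping during
#' contig extraction instead.
#'
#' @param reads Character vector of read sequences (A/C/G/T/N).
#' @param k Odd k-mer size between 11 and 63 (default 21).
#' @param min_count Minimum k-mer multiplicity for an edge to survive
#'   (default 2).
#' @return An object of class `debruijn_graph`: list with `k` and `edges`
#'   (named integer vector of k-mer multiplicities, both orientations).
#' @export
build_graph <- function(reads, k = 21, min_count = 2) {
  if (k %% 2 == 0 || k < 11 || k > 63) abort("k must be odd and in [11, 63]")
  reads <- toupper(reads)
  frags <- unlist(strsplit(reads, "N+"), use.names = FALSE)
  frags <- frags[nchar(frags) >= k]
  frags <- c(frags, reverse_complement(frags))
  kmers <- unlist(lapply(frags, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  counts <- table(kmers)
  counts <- counts[counts >= min_count]
  edges <- as.integer(counts)
  names(edges) <- names(counts)
  structure(list(k = k, edges = edges), class = "debruijn_graph")
}

#' Number of edges of a de Bruijn graph
#'
#' @param g A `debruijn_graph`.
#' @param canonical Count each k-mer/reverse-complement pair once (default).
#' @return Integer edge count.
#' @export
n_edges <- function(g, canonical = TRUE) {
  km <- names(g$edges)
  if (length(km) == 0) return(0L)
  if (!canonical) return(length(km))
  length(unique(pmin(km, reverse_complement(km))))
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf("# de Bruijn graph: k = %d, %d edges (%d canonical)\n",
              x$k, length(x$edges), n_edges(x)))
  invisible(x)
}

# Extract maximal non-branching paths from an edge table. Deterministic:
# edges are visited in lexicographic k-mer order. Nodes are handled as
# integer indices so every lookup is O(1).
extract_paths <- function(kmer, count, k) {
  o <- order(kmer)
  kmer <- kmer[o]; count <- count[o]
  from <- substring(kmer, 1, k - 1)
  to <- substring(kmer, 2, k)
  nodes <- sort(unique(c(from, to)))
  fi <- match(from, nodes)
  ti <- match(to, nodes)
  out_deg <- tabulate(fi, length(nodes))
  in_deg <- tabulate(ti, length(nodes))
  out_list <- vector("list", length(nodes))
  sp <- split(seq_along(kmer), fi)
  out_list[as.integer(names(sp))] <- sp
  simple <- out_deg == 1L & in_deg == 1L
  used <- logical(length(kmer))
  paths <- list()
  walk_from <- function(i) {
    path <- integer(64); path[1] <- i; np <- 1L
    used[i] <<- TRUE
    cur <- ti[i]
    repeat {
      if (!simple[cur]) break
      nxt <- out_list[[cur]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      j <- nxt[1]
      np <- np + 1L
      if (np > length(path)) path <- c(path, integer(length(path)))
      path[np] <- j
      used[j] <<- TRUE
      cur <- ti[j]
    }
    path[seq_len(np)]
  }
  for (i in seq_along(kmer)) {
    if (used[i] || simple[fi[i]]) next
    paths[[length(paths) + 1L]] <- walk_from(i)
  }
  # leftover edges belong to isolated cycles of simple nodes
  for (i in seq_along(kmer)) {
    if (used[i]) next
    paths[[length(paths) + 1L]] <- walk_from(i)
  }
  lapply(paths, function(p) {
    list(kmers = kmer[p], counts = count[p],
         seq = paste0(from[p[1]], paste(substring(kmer[p], k, k), collapse = "")),
         start_node = from[p[1]], end_node = to[p[length(p)]],
         start_in_deg = in_deg[fi[p[1]]],
         end_out_deg = out_deg[ti[p[length(p)]]])
  })
}

#' Assemble contigs from a de Bruijn graph
#'
#' One contig per maximal non-branching path, visited in deterministic
#' lexicographic order (assembly output is reproducible without a seed).
#' Before final extraction, short low-coverage dead-end paths (tips) and
#' short low-coverage alternative paths (bubbles, the signature of isolated
#' substitution errors) are clipped for `clip_rounds` rounds. Each contig
#' and its reverse complement collapse to one record (the lexicographically
#' smaller orientation is kept); `graph_neighbors` lists the contigs that
#' share a branch node with it in either orientation.
#'
#' @param g A [build_graph()] result.
#' @param clip_rounds Tip/bubble clipping rounds (default 2; 0 disables).
#' @param clip_cov Paths with mean k-mer coverage below this are clippable
#'   (default 2).
#' @param clip_len Paths shorter than this many bases are clippable
#'   (default `3 * k`).
#' @return A tibble with columns `contig_id`, `sequence`, `length`,
#'   `mean_coverage`, `start_node`, `end_node`, `graph_neighbors`
#'   (list-column of contig ids).
#' @export
assemble_contigs <- function(g, clip_rounds = 2, clip_cov = 2,
                             clip_len = 3 * g$k) {
  k <- g$k
  kmer <- names(g$edges)
  count <- as.integer(g$edges)
  empty <- tibble(contig_id = character(), sequence = character(),
                  length = integer(), mean_coverage = double(),
                  start_node = character(), end_node = character(),
                  graph_neighbors = list())
  if (length(kmer) == 0) return(empty)
  round <- 0
  repeat {
    paths <- extract_paths(kmer, count, k)
    if (round >= clip_rounds) break
    is_tip <- vapply(paths, function(p) {
      dead_end <- p$start_in_deg == 0 || p$end_out_deg == 0
      short <- nchar(p$seq) < clip_len
      low <- mean(p$counts) < clip_cov
      low && short && dead_end
    }, logical(1))
    # bubbles: short low-coverage paths between branch nodes whose removal
    # keeps both terminals connected through a better-covered alternative
    is_bubble <- vapply(paths, function(p) {
      internal <- p$start_in_deg >= 1 && p$end_out_deg >= 1
      short <- nchar(p$seq) < clip_len
      low <- mean(p$counts) < clip_cov
      low && short && internal
    }, logical(1))
    drop <- is_tip | is_bubble
    if (!any(drop) || all(drop)) break
    dropped <- unlist(lapply(paths[drop], `[[`, "kmers"), use.names = FALSE)
    keep <- !(kmer %in% dropped)
    kmer <- kmer[keep]; count <- count[keep]
    if (length(kmer) == 0) return(empty)
    round <- round + 1
  }
  seqs <- vapply(paths, `[[`, "", "seq")
  rc <- reverse_complement(seqs)
  canon <- pmin(seqs, rc)
  flip <- canon != seqs
  start_node <- vapply(paths, `[[`, "", "start_node")
  end_node <- vapply(paths, `[[`, "", "end_node")
  s2 <- ifelse(flip, reverse_complement(end_node), start_node)
  e2 <- ifelse(flip, reverse_complement(start_node), end_node)
  covs <- vapply(paths, function(p) mean(p$counts), numeric(1))
  keep <- !duplicated(canon)
  contigs <- tibble(
    sequence = canon[keep], length = nchar(canon[keep]),
    mean_coverage = covs[keep], start_node = s2[keep], end_node = e2[keep]
  )
  contigs <- arrange(contigs, dplyr::desc(.data$length), .data$sequence)
  contigs$contig_id <- sprintf("ctg%04d", seq_len(nrow(contigs)))
  # contigs sharing a terminal (k-1)-mer in either orientation are neighbors
  node_sets <- lapply(seq_len(nrow(contigs)), function(i) {
    unique(c(contigs$start_node[i], contigs$end_node[i],
             reverse_complement(c(contigs$start_node[i], contigs$end_node[i]))))
  })
  contigs$graph_neighbors <- lapply(seq_len(nrow(contigs)), function(i) {
    hits <- vapply(seq_len(nrow(contigs)), function(j) {
      j != i && length(intersect(node_sets[[i]], node_sets[[j]])) > 0
    }, logical(1))
    contigs$contig_id[hits]
  })
  contigs[, c("contig_id", "sequence", "length", "mean_coverage",
              "start_node", "end_node", "graph_neighbors")]
}
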