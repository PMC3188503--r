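# Inheritance, mutation, and ancestor-lineage analysis.

#' Mutation specification
#'
#' Each evolvable gene mutates independently at birth with probability
#' `rate` (0.05 by default); the offspring value is drawn from a normal
#' distribution centered on the mother's value with a per-gene standard
#' deviation of about 20% of the gene's reasonable range, then clamped to the
#' gene's bounds (see [gene_bounds()]). Non-evolvable quantities (reach,
#' handling time, the architecture itself) never mutate; the restricted
#' architecture additionally holds `p_se`, `p_sn` and `p_mtf` fixed and the
#' extended architecture holds `p_ss` fixed.
#'
#' @param rate per-gene mutation probability.
#' @param sd named numeric vector of per-gene step standard deviations
#'   overriding the defaults.
#' @return A `mutation_spec` with vectors `sd`, `lo`, `hi` aligned to the
#'   engine's gene layout.
#' @export
mutation_spec <- function(rate = 0.05, sd = NULL) {
  b <- gene_bounds()
  s <- setNames(b$sd, b$gene)
  if (!is.null(sd)) s[names(sd)] <- sd
  structure(list(
    rate = rate,
    sd = c(0, unname(s)),           # leading 0: the `kind` slot never mutates
    lo = c(0, b$min),
    hi = c(1, ifelse(is.finite(b$max), b$max, .Machine$double.xmax))
  ), class = "mutation_spec")
}

#' Mutate a genotype
#'
#' Reference R implementation of inheritance (the engine applies the same
#' scheme internally at each birth). Out-of-bound draws are clamped to the
#' bound.
#'
#' @param g a [genotype()].
#' @param spec a [mutation_spec()].
#' @return The offspring [genotype()].
#' @export
mutate <- function(g, spec = mutation_spec()) {
  b <- gene_bounds()
  fixed <- if (g$kind == "restricted") c("p_se", "p_sn", "p_mtf") else "p_ss"
  sd_by_gene <- spec$sd[-1]
  for (i in seq_len(nrow(b))) {
    gene <- b$gene[i]
    if (gene %in% fixed) next
    if (runif(1) >= spec$rate) next
    v <- rnorm(1, mean = g[[gene]], sd = sd_by_gene[i])
    g[[gene]] <- min(max(v, b$min[i]), b$max[i])
  }
  validate_genotype(unclass(g))
}

#' Trace ancestors of final individuals
#'
#' Walks parent links from each of `final_ids` back to a founder, yielding
#' the time-stamped genotype path of every surviving lineage.
#'
#' @param lineage the `lineage` data.frame of a [simulate_foraging()] result
#'   (columns `child_id`, `parent_id`, `birth_time`, gene columns).
#' @param final_ids ids to trace from (e.g. the ids alive at the end).
#' @return data.frame of the union of lineages: `lineage_id` (the final id
#'   the path leads to), `child_id`, `parent_id`, `birth_time` and the gene
#'   columns, ordered root-to-tip within lineage.
#' @export
trace_ancestors <- function(lineage, final_ids) {
  if (!all(final_ids %in% lineage$child_id))
    stop("some final ids are absent from the lineage archive")
  paths <- lapply(final_ids, function(fid) {
    chain <- integer()
    cur <- fid
    repeat {
      i <- match(cur, lineage$child_id)
      if (is.na(i))
        stop("missing parent link for id ", cur, " (corrupt archive)")
      chain <- c(chain, i)
      p <- lineage$parent_id[i]
      if (is.na(p)) break
      cur <- p
    }
    cbind(lineage_id = fid, lineage[rev(chain), , drop = FALSE])
  })
  out <- do.call(rbind, paths)
  rownames(out) <- NULL
  out
}

#' Evolved genotype: window average along surviving lineages
#'
#' Per-gene mean and standard deviation over all distinct ancestors whose
#' birth time falls inside the year window (the convention for reading an
#' evolved attractor off a finished run: a window well before the end
#' excludes recent mutants that selection has not yet filtered).
#'
#' @param traces result of [trace_ancestors()] (or a lineage data.frame).
#' @param window numeric length-2, year range `[lo, hi)` measured from time
#'   zero.
#' @param year_length minutes per year used to convert `birth_time`.
#' @return list with `mean` and `sd`: named numeric vectors over the genes,
#'   plus `n`, the number of distinct ancestors averaged.
#' @export
evolved_genotype <- function(traces, window, year_length = 365 * 720) {
  stopifnot(length(window) == 2, window[1] < window[2])
  yr <- traces$birth_time / year_length
  sel <- traces[yr >= window[1] & yr < window[2], , drop = FALSE]
  sel <- sel[!duplicated(sel$child_id), , drop = FALSE]
  if (nrow(sel) == 0) stop("no ancestors born inside the window")
  genes <- GENE_NAMES[-1]
  list(mean = vapply(sel[genes], mean, numeric(1)),
       sd = vapply(sel[genes], sd, numeric(1)),
       n = nrow(sel))
}

#' Write / read a lineage archive as TSV
#'
#' @param lineage lineage data.frame (see [trace_ancestors()]).
#' @param path file path.
#' @export
write_lineage <- function(lineage, path) {
  write.table(lineage, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lineage
#' @export
read_lineage <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
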