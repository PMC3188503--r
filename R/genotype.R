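# Genotypes: the evolvable parameter vector of a forager.

GENE_NAMES <- c("kind", "t_m", "t_fs", "d_m", "d_fs", "a_t", "a_fs",
                "p_mm", "p_ss", "p_se", "p_sn", "p_mtf")

#' Per-gene bounds and default mutation step sizes
#'
#' Durations are bounded to \[0.167, 1.99\] minutes (the 10-second minimal
#' action duration, and a programming-convenience maximum high enough not to
#' bind), distances are non-negative and unbounded above, angles live in
#' \[0, 360\] degrees, probabilities in \[0, 1\]. Mutation standard deviations
#' default to 20% of a reasonable range for each gene class: 0.4 min for
#' durations (0.2 of a 2-min range), 2 m for distances (0.2 of 10 m), 72
#' degrees for angles, 0.2 for probabilities.
#'
#' @return A data.frame with columns `gene`, `min`, `max`, `sd`.
#' @export
gene_bounds <- function() {
  data.frame(
    gene = GENE_NAMES[-1],
    min = c(0.167, 0.167, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    max = c(1.99, 1.99, Inf, Inf, 360, 360, 1, 1, 1, 1, 1),
    sd = c(0.4, 0.4, 2, 2, 72, 72, 0.2, 0.2, 0.2, 0.2, 0.2),
    stringsAsFactors = FALSE
  )
}

#' Construct a forager genotype
#'
#' @param kind `"restricted"` or `"extended"`. The restricted architecture has
#'   a single outcome-blind probability `p_ss` of repeating FOODSCAN and always
#'   approaches detected out-of-reach food (`p_mtf` is fixed at 1); the
#'   extended architecture splits the repeat-scan probability into `p_se`
#'   (after EAT) and `p_sn` (after a scan that found nothing) and lets `p_mtf`
#'   evolve.
#' @param t_m,t_fs MOVE and FOODSCAN durations (min), clamped to
#'   \[0.167, 1.99\].
#' @param d_m,d_fs MOVE step distance and FOODSCAN radius (m), non-negative.
#' @param a_t,a_fs turning angle and full scan-sector angle (degrees, 0-360).
#'   The scan sector spans `a_fs/2` either side of the heading.
#' @param p_mm probability of repeating MOVE.
#' @param p_ss restricted-model probability of repeating FOODSCAN
#'   (outcome-blind).
#' @param p_se,p_sn extended-model probabilities of repeating FOODSCAN after
#'   EAT and after NO FOOD.
#' @param p_mtf probability of approaching detected out-of-reach food.
#'
#' The default is the "zero" initial state used to seed evolutionary runs:
#' every gene at its lower bound (durations bind at the 0.167-min minimum).
#'
#' @return An object of class `forevol_genotype` (a named list).
#' @export
genotype <- function(kind = c("restricted", "extended"),
                     t_m = 0.167, t_fs = 0.167, d_m = 0, d_fs = 0,
                     a_t = 0, a_fs = 0, p_mm = 0, p_ss = 0,
                     p_se = 0, p_sn = 0, p_mtf = 1) {
  kind <- match.arg(kind)
  g <- list(kind = kind, t_m = t_m, t_fs = t_fs, d_m = d_m, d_fs = d_fs,
            a_t = a_t, a_fs = a_fs, p_mm = p_mm, p_ss = p_ss,
            p_se = p_se, p_sn = p_sn, p_mtf = p_mtf)
  validate_genotype(g)
}

validate_genotype <- function(g) {
  b <- gene_bounds()
  for (i in seq_len(nrow(b))) {
    v <- g[[b$gene[i]]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("gene '", b$gene[i], "' must be a single number")
    if (v < b$min[i] - 1e-12 || v > b$max[i] + 1e-12)
      stop("gene '", b$gene[i], "' = ", v, " outside [",
           b$min[i], ", ", b$max[i], "]")
  }
  if (g$kind == "restricted") {
    g$p_mtf <- 1        # always MOVETOFOOD when food is out of reach
    g$p_se <- 0; g$p_sn <- 0
  } else {
    g$p_ss <- 0
  }
  class(g) <- "forevol_genotype"
  g
}

#' @export
print.forevol_genotype <- function(x, ...) {
  cat("<forevol_genotype>", x$kind, "model\n")
  v <- unlist(x[GENE_NAMES[-1]])
  cat(paste0("  ", format(names(v), width = 6), " = ",
             format(v, digits = 4)), sep = "\n")
  invisible(x)
}

# genotype(s) -> numeric matrix in the engine's column layout
genotype_matrix <- function(genotypes) {
  if (inherits(genotypes, "forevol_genotype")) genotypes <- list(genotypes)
  m <- matrix(0, nrow = length(genotypes), ncol = length(GENE_NAMES),
              dimnames = list(NULL, GENE_NAMES))
  for (i in seq_along(genotypes)) {
    g <- genotypes[[i]]
    m[i, 1] <- if (g$kind == "extended") 1 else 0
    m[i, -1] <- unlist(g[GENE_NAMES[-1]])
  }
  m
}

matrix_to_genotypes <- function(m) {
  lapply(seq_len(nrow(m)), function(i) {
    g <- as.list(m[i, -1])
    g <- c(list(kind = if (m[i, 1] >= 0.5) "extended" else "restricted"), g)
    validate_genotype(g)
  })
}

#' Synthetic specialist genotypes
#'
#' One representative evolved genotype per model-by-environment combination
#' (R-Patchy, R-Uni, Ext-Patchy, Ext-Uni). These are *synthetic* stand-ins:
#' parameter values were fixed from the qualitative features of the evolved
#' attractors (extended specialists always rescan after eating and never after
#' finding nothing; the restricted patch specialist has an intermediate
#' repeat-scan probability, the shortest move distance and a full-circle scan;
#' the restricted uniform specialist never rescans; the extended uniform
#' specialist moves 1.35 times further than its restricted counterpart; the
#' extended patch specialist has by far the longest move step and is the only
#' one to repeat MOVE and turn while moving; scan radius near the 2--2.5 m
#' convergence band; durations at the 0.167-min minimum), not from a fitted
#' table of evolved means.
#'
#' @return Named list of four [genotype()] objects:
#'   `R-Patchy`, `R-Uni`, `Ext-Patchy`, `Ext-Uni`.
#' @export
specialist_genotypes <- function() {
  list(
    "R-Patchy" = genotype("restricted", t_m = 0.167, t_fs = 0.167,
                          d_m = 1.0, d_fs = 2.2, a_t = 0, a_fs = 360,
                          p_mm = 0, p_ss = 0.45),
    "R-Uni" = genotype("restricted", t_m = 0.167, t_fs = 0.167,
                       d_m = 2.0, d_fs = 2.2, a_t = 0, a_fs = 270,
                       p_mm = 0, p_ss = 0.02),
    "Ext-Patchy" = genotype("extended", t_m = 0.167, t_fs = 0.167,
                            d_m = 8.0, d_fs = 2.2, a_t = 25, a_fs = 180,
                            p_mm = 0.35, p_se = 1, p_sn = 0, p_mtf = 1),
    "Ext-Uni" = genotype("extended", t_m = 0.167, t_fs = 0.167,
                         d_m = 2.7, d_fs = 2.2, a_t = 0, a_fs = 270,
                         p_mm = 0, p_se = 1, p_sn = 0, p_mtf = 1)
  )
}

#' Write / read genotypes as TSV
#'
#' One row per genotype; columns are `name`, `model_kind` and the gene names
#' `t_m, t_fs, d_m, d_fs, a_t, a_fs, p_mm, p_ss, p_se, p_sn, p_mtf`.
#'
#' @param genotypes a named list of [genotype()] objects.
#' @param path file path.
#' @return `read_genotypes()` returns a named list of genotypes.
#' @export
write_genotypes <- function(genotypes, path) {
  m <- genotype_matrix(genotypes)
  df <- data.frame(name = names(genotypes) %||% seq_along(genotypes),
                   model_kind = ifelse(m[, "kind"] >= 0.5,
                                       "extended", "restricted"))
  df <- cbind(df, as.data.frame(m[, -1, drop = FALSE]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    g <- as.list(df[i, GENE_NAMES[-1]])
    g <- c(list(kind = df$model_kind[i]), lapply(g, as.numeric))
    validate_genotype(g)
  })
  names(out) <- df$name
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
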