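#' Enumerate amino-acid change types reachable by single base substitutions
#'
#' Walks every single-base neighbour of every codon of the genetic code and
#' collects the distinct coding-change types, split into five classes:
#' residue-to-residue (missense), residue-to-stop (nonsense), stop-to-residue
#' (make-sense), start-codon elimination (`ATG` mutated away from
#' methionine) and its mirror, start-codon creation.  The start classes are
#' counted separately from plain `M` missense exchanges because the start
#' codon plays a distinct functional role.  Under the standard code the
#' classes hold 150, 10, 10, 6 and 6 distinct types: 182 in total.
#'
#' @param code genetic code (named character vector codon -> one-letter
#'   residue, `*` for stop).  Start codon is taken to be `ATG` when present
#'   in the code.
#' @return An `aa_change_types` list with `classes` (named list of type
#'   vectors), `counts` (per-class) and `total` (distinct overall count,
#'   summing the class counts).
#' @export
#' @examples
#' enumerate_aa_change_types()$total  # 182
enumerate_aa_change_types <- function(code = Biostrings::GENETIC_CODE) {
  codons <- names(code)
  if (is.null(codons) || any(nchar(codons) != 3L)) {
    stop("malformed codon table: names must be codons")
  }
  if (any(!grepl("^[ACGT]{3}$", codons))) {
    stop("malformed codon table: non-ACGT codons")
  }
  has_start <- "ATG" %in% codons
  # all 9 single-base neighbours of every codon, vectorised
  cd <- rep(codons, each = 9L)
  pos <- rep(rep(1:3, each = 3L), times = length(codons))
  alt_of <- lapply(.BASES, function(b) setdiff(.BASES, b))
  names(alt_of) <- .BASES
  to <- unlist(lapply(codons, function(x)
    unlist(alt_of[strsplit(x, "")[[1]]], use.names = FALSE)),
    use.names = FALSE)
  cd2 <- cd
  substr(cd2, pos, pos) <- to
  keep <- cd2 %in% codons  # neighbours outside a degenerate code are skipped
  cd <- cd[keep]; cd2 <- cd2[keep]
  aa1 <- unname(code[cd]); aa2 <- unname(code[cd2])
  keep <- aa1 != aa2
  cd <- cd[keep]; cd2 <- cd2[keep]; aa1 <- aa1[keep]; aa2 <- aa2[keep]
  ty <- paste0(aa1, ">", aa2)
  nonsense <- ty[aa1 != "*" & aa2 == "*"]
  make_sense <- ty[aa1 == "*" & aa2 != "*"]
  missense <- ty[aa1 != "*" & aa2 != "*"]
  start_loss <- if (has_start) {
    paste0("Mstart>", aa2[cd == "ATG" & aa2 != "*"])
  } else character(0)
  start_gain <- if (has_start) {
    paste0(aa1[cd2 == "ATG" & aa1 != "*"], ">Mstart")
  } else character(0)
  classes <- list(missense = sort(unique(missense)),
                  nonsense = sort(unique(nonsense)),
                  make_sense = sort(unique(make_sense)),
                  start_loss = sort(unique(start_loss)),
                  start_gain = sort(unique(start_gain)))
  counts <- vapply(classes, length, integer(1))
  structure(list(classes = classes, counts = counts,
                 total = sum(counts)),
            class = "aa_change_types")
}

#' @export
print.aa_change_types <- function(x, ...) {
  cat("Coding-change types reachable by single nucleotide substitution\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-11s %3d\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  %-11s %3d\n", "total", x$total))
  invisible(x)
}

#' Build an amino-acid change matrix from consequence calls
#'
#' Collects `from > to` residue-change counts over the coding (non-splicing)
#' calls: missense, nonsense (residue to `*`), make-sense and start-loss.
#'
#' @param calls consequence-call data.frame (or `consequence_set`).
#' @param dataset optional dataset filter.
#' @return An `aa_change_matrix`: data.frame with columns `from`, `to`,
#'   `type`, `count`; attribute `dataset`.
#' @export
aa_change_matrix <- function(calls, dataset = NULL) {
  if (inherits(calls, "consequence_set")) calls <- calls$calls
  keep <- calls$category %in%
    c("missense", "nonsense", "make_sense", "start_loss") &
    !is.na(calls$aa_from) & !is.na(calls$aa_to)
  if (!is.null(dataset)) keep <- keep & calls$dataset %in% dataset
  sub <- calls[keep, ]
  if (any(sub$aa_from == sub$aa_to)) {
    stop("diagonal (synonymous) entries are not allowed")
  }
  tab <- as.data.frame(table(from = sub$aa_from, to = sub$aa_to),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "count"
  tab <- tab[tab$count > 0L, ]
  tab$type <- paste0(tab$from, ">", tab$to)
  rownames(tab) <- NULL
  structure(tab[, c("from", "to", "type", "count")],
            dataset = if (is.null(dataset)) "all" else
              paste(dataset, collapse = "+"),
            class = c("aa_change_matrix", "data.frame"))
}

#' Construct an amino-acid change matrix from explicit counts
#'
#' @param types character vector like `"S>P"`.
#' @param counts integer counts, same length.
#' @param dataset label.
#' @return An `aa_change_matrix`.
#' @export
as_aa_change_matrix <- function(types, counts, dataset = "unlabeled") {
  from <- sub(">.*$", "", types)
  to <- sub("^.*>", "", types)
  if (any(from == to)) stop("diagonal entries are not allowed")
  structure(data.frame(from = from, to = to, type = types,
                       count = as.integer(counts),
                       stringsAsFactors = FALSE),
            dataset = dataset, class = c("aa_change_matrix", "data.frame"))
}

#' Compare phenotypic and incidental amino-acid change spectra
#'
#' For every change type observed in either set, computes its relative
#' frequency among all changes of each set and a two-sided exact test on the
#' 2x2 table (this type vs the rest, by dataset), flagging types enriched in
#' one set at the chosen level (unadjusted).
#'
#' @param phenotypic,incidental `aa_change_matrix` objects.
#' @param alpha significance level for the enrichment flag (default 0.05).
#' @return An `aa_comparison` data.frame with columns `type`,
#'   `count_phenotypic`, `count_incidental`, `freq_phenotypic`,
#'   `freq_incidental`, `p_value`, `direction`
#'   (`"phenotypic"`/`"incidental"`/`"none"`), `significant`.
#' @export
compare_aa_spectra <- function(phenotypic, incidental, alpha = 0.05) {
  if (nrow(phenotypic) == 0L || nrow(incidental) == 0L) {
    stop("both change matrices must be non-empty")
  }
  np <- sum(phenotypic$count)
  ni <- sum(incidental$count)
  types <- sort(union(phenotypic$type, incidental$type))
  kp <- setNames(rep(0L, length(types)), types)
  kp[phenotypic$type] <- phenotypic$count
  ki <- setNames(rep(0L, length(types)), types)
  ki[incidental$type] <- incidental$count
  p_val <- vapply(types, function(ty) {
    stats::fisher.test(matrix(c(kp[[ty]], np - kp[[ty]],
                                ki[[ty]], ni - ki[[ty]]), nrow = 2L))$p.value
  }, numeric(1))
  fp <- kp / np
  fi <- ki / ni
  dir <- ifelse(fp > fi, "phenotypic", ifelse(fi > fp, "incidental", "none"))
  out <- data.frame(type = types,
                    count_phenotypic = as.integer(kp),
                    count_incidental = as.integer(ki),
                    freq_phenotypic = as.numeric(fp),
                    freq_incidental = as.numeric(fi),
                    p_value = as.numeric(p_val),
                    direction = dir,
                    significant = p_val < alpha & dir != "none",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("aa_comparison", "data.frame")
  out
}

#' Scatter of amino-acid change frequencies, phenotypic vs incidental
#'
#' Convenience plot: each point is one change type, the diagonal marks equal
#' frequency, and types flagged as significantly enriched are labelled.
#'
#' @param comparison an `aa_comparison`.
#' @param ... passed to `plot.default`.
#' @return The comparison, invisibly.
#' @export
plot_aa_comparison <- function(comparison, ...) {
  graphics::plot.default(
    comparison$freq_incidental, comparison$freq_phenotypic,
    xlab = "frequency among incidental changes",
    ylab = "frequency among phenotypic changes",
    pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  sig <- comparison[comparison$significant, ]
  if (nrow(sig)) {
    graphics::text(sig$freq_incidental, sig$freq_phenotypic, sig$type,
                   pos = 3, cex = 0.7)
  }
  invisible(comparison)
}
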