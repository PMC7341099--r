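MAX_DOCKING_MODES <- 9L

#' DockingResult: parsed binding modes of one docked molecule
#'
#' Mode affinities are binding free energies (kcal/mol) of up to nine
#' conformations reported by a docking search.
#'
#' @slot moleculeId molecule identifier
#' @slot receptorTag free-text receptor label
#' @slot modes data.frame with `mode`, `affinity`
#' @exportClass DockingResult
setClass("DockingResult",
  representation(moleculeId = "character", receptorTag = "character",
                 modes = "data.frame"))

setValidity("DockingResult", function(object) {
  m <- object@modes
  if (nrow(m) < 1L || nrow(m) > MAX_DOCKING_MODES)
    return("between 1 and 9 modes required")
  if (any(!is.finite(m$affinity))) return("non-finite affinity")
  TRUE
})

setMethod("show", "DockingResult", function(object) {
  cat(sprintf("DockingResult '%s': %d modes, mean %.3f kcal/mol\n",
              object@moleculeId, nrow(object@modes),
              mean(object@modes$affinity)))
})

#' Parse a docking log into a DockingResult
#'
#' Reads the standard text table dialect
#' (`mode | affinity (kcal/mol) | rmsd ...` header followed by numbered
#' rows), tolerant of banner text around the table. Only the first nine
#' modes are retained (the search reports at most nine conformations).
#'
#' @param x path to a log file, or the log text as a character vector
#' @param moleculeId identifier (default: file base name)
#' @param receptorTag optional receptor label
#' @return a [DockingResult-class]
#' @export
parseDockingLog <- function(x, moleculeId = NULL, receptorTag = "") {
  lines <- if (length(x) == 1L && file.exists(x)) {
    if (is.null(moleculeId))
      moleculeId <- tools::file_path_sans_ext(basename(x))
    readLines(x)
  } else {
    if (length(x) == 1L) x <- strsplit(x, "\n")[[1]]
    x
  }
  if (is.null(moleculeId)) moleculeId <- "molecule"
  rows <- regmatches(lines,
                     regexec("^\\s*(\\d+)\\s+(-?\\d+(?:\\.\\d+)?)\\s", lines))
  rows <- Filter(length, rows)
  if (!length(rows))
    stop("no binding-mode table found in docking log for ", moleculeId)
  modes <- data.frame(
    mode = vapply(rows, function(r) as.integer(r[2]), integer(1)),
    affinity = vapply(rows, function(r) as.numeric(r[3]), numeric(1)))
  if (nrow(modes) > MAX_DOCKING_MODES)
    modes <- modes[seq_len(MAX_DOCKING_MODES), , drop = FALSE]
  new("DockingResult", moleculeId = as.character(moleculeId),
      receptorTag = receptorTag, modes = modes)
}

#' Average binding energy over docking modes
#'
#' The structure-based score of a candidate: the arithmetic mean of its
#' per-mode binding affinities.
#'
#' @param result a [DockingResult-class]
#' @return mean affinity in kcal/mol
#' @examples
#' r <- parseDockingLog(c("mode | affinity | rmsd", "  1  -7.1  0.0",
#'                        "  2  -6.9  1.2", "  3  -6.5  2.0"), "m1")
#' averageBindingEnergy(r)  # -6.8333...
#' @export
averageBindingEnergy <- function(result) {
  if (!nrow(result@modes)) stop("no modes")
  mean(result@modes$affinity)
}

#' Combine knowledge-based and structure-based rankings
#'
#' Ranks candidates by classifier probability (descending) and by mean
#' binding affinity (ascending: more negative is better), then combines
#' the two rank lists. `"ranksum"` (default) orders by the sum of ranks;
#' `"borda"` by the sum of Borda scores (equivalent ordering, kept as an
#' explicit alternative); `"topk_intersection"` puts candidates in both
#' top-k lists first (by rank sum), then the rest. Ties break by the
#' better knowledge-based rank, then `molecule_id`. `dual_high` flags
#' candidates in the top `topK` of both lists.
#'
#' @param kb data.frame with `molecule_id`, `probability`
#' @param sb data.frame with `molecule_id`, `mean_affinity`
#' @param method combination rule
#' @param topK cutoff for the `dual_high` flag (default 10)
#' @return data.frame with per-candidate scores, `kb_rank`, `sb_rank`,
#'   `combined_rank`, `dual_high`, ordered by `combined_rank`
#' @export
combineRankings <- function(kb, sb,
                            method = c("ranksum", "borda",
                                       "topk_intersection"),
                            topK = 10L) {
  method <- match.arg(method)
  if (!setequal(kb$molecule_id, sb$molecule_id)) {
    miss <- c(setdiff(kb$molecule_id, sb$molecule_id),
              setdiff(sb$molecule_id, kb$molecule_id))
    stop("molecule universes differ; missing ids: ",
         paste(miss, collapse = ", "))
  }
  kb <- kb[order(-kb$probability, kb$molecule_id), , drop = FALSE]
  kb$kb_rank <- seq_len(nrow(kb))
  sb <- sb[order(sb$mean_affinity, sb$molecule_id), , drop = FALSE]
  sb$sb_rank <- seq_len(nrow(sb))
  df <- merge(kb, sb, by = "molecule_id")
  n <- nrow(df)
  df$rank_sum <- df$kb_rank + df$sb_rank
  inBoth <- df$kb_rank <= topK & df$sb_rank <= topK
  key <- switch(method,
    ranksum = df$rank_sum,
    borda = 2 * n - df$rank_sum,           # larger is better
    topk_intersection = ifelse(inBoth, df$rank_sum, df$rank_sum + 2 * n))
  decreasing <- method == "borda"
  ord <- order(if (decreasing) -key else key, df$kb_rank, df$molecule_id)
  df <- df[ord, , drop = FALSE]
  df$combined_rank <- seq_len(n)
  df$dual_high <- df$kb_rank <= topK & df$sb_rank <= topK
  rownames(df) <- NULL
  df[, c("molecule_id", "probability", "kb_rank", "mean_affinity",
         "sb_rank", "rank_sum", "combined_rank", "dual_high")]
}
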