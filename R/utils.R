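## Interval algebra on 0-based half-open [start, end) bp intervals,
## represented as two-column matrices (start, end). Empty set = 0-row matrix.

iv <- function(start, end) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  m[m[, 1] < m[, 2], , drop = FALSE]
}

iv_empty <- function() iv(numeric(0), numeric(0))

#' @noRd
iv_normalize <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out_s <- m[1, 1]; out_e <- m[1, 2]
  res <- list()
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] <= out_e) {
        out_e <- max(out_e, m[i, 2])
      } else {
        res[[length(res) + 1L]] <- c(out_s, out_e)
        out_s <- m[i, 1]; out_e <- m[i, 2]
      }
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  colnames(m) <- c("start", "end")
  m
}

iv_union <- function(a, b) iv_normalize(rbind(a, b))

## a minus b, both normalized
iv_setdiff <- function(a, b) {
  a <- iv_normalize(a); b <- iv_normalize(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1]; e <- a[i, 2]
    for (j in seq_len(nrow(b))) {
      bs <- b[j, 1]; be <- b[j, 2]
      if (be <= s || bs >= e) next
      if (bs > s) out[[length(out) + 1L]] <- c(s, min(bs, e))
      s <- max(s, be)
      if (s >= e) break
    }
    if (s < e) out[[length(out) + 1L]] <- c(s, e)
  }
  if (length(out) == 0L) return(iv_empty())
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  iv_normalize(m)
}

iv_width <- function(m) if (nrow(m) == 0L) 0 else sum(m[, 2] - m[, 1])

iv_hull <- function(m) {
  if (nrow(m) == 0L) return(iv_empty())
  iv(min(m[, 1]), max(m[, 2]))
}

iv_overlaps <- function(m, start, end) {
  nrow(m) > 0L && any(m[, 1] < end & m[, 2] > start)
}

#' Does a point fall inside any interval of a half-open interval set?
#'
#' @param m Two-column interval matrix (start, end), half-open.
#' @param p Position in bp.
#' @return Logical scalar.
#' @export
iv_contains_point <- function(m, p) {
  nrow(m) > 0L && any(m[, 1] <= p & p < m[, 2])
}

## Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Reverse complement of a plain character DNA string (hot-loop safe).
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
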