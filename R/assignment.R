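#' Minimum-cost bipartite assignment
#'
#' Solves the rectangular linear sum assignment problem (every row assigned
#' to a distinct column, total cost minimised) with the Jonker--Volgenant
#' shortest-augmenting-path algorithm, O(n^2 m). Used by the CLEAR-MOT and
#' IDF1 evaluators, which need a *weighted* optimal matching; greedy
#' association in the tracker deliberately does not use it.
#'
#' @param cost numeric matrix (finite entries). If it has more rows than
#'   columns it is solved transposed.
#' @return Integer vector of length `nrow(cost)`: `result[i]` is the column
#'   assigned to row `i` (`NA` only possible when `nrow > ncol`, for rows
#'   left unassigned — never for a square or wide matrix).
#' @examples
#' solve_assignment(matrix(c(4, 1, 3, 2, 0, 5, 3, 2, 2), 3, 3))
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || !all(is.finite(cost)))
    stop("cost must be a finite numeric matrix")
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L) return(integer())
  if (nr > nc) {
    col4row <- solve_assignment(t(cost))
    out <- rep(NA_integer_, nr)
    out[col4row] <- seq_len(nc)
    return(out)
  }
  u <- numeric(nr); v <- numeric(nc)
  col4row <- rep(NA_integer_, nr)   # column assigned to each row
  row4col <- rep(NA_integer_, nc)   # row assigned to each column
  for (cur_row in seq_len(nr)) {
    # Dijkstra over reduced costs from cur_row to a free column
    shortest <- rep(Inf, nc)
    path <- rep(NA_integer_, nc)
    SR <- logical(nr); SC <- logical(nc)
    remaining <- seq_len(nc)
    min_val <- 0
    i <- cur_row
    sink <- NA_integer_
    while (is.na(sink)) {
      SR[i] <- TRUE
      r <- min_val + cost[i, remaining] - u[i] - v[remaining]
      upd <- r < shortest[remaining]
      if (any(upd)) {
        jj <- remaining[upd]
        shortest[jj] <- r[upd]
        path[jj] <- i
      }
      sp <- shortest[remaining]
      lowest <- min(sp)
      if (!is.finite(lowest)) stop("assignment infeasible")
      cand <- remaining[sp == lowest]
      free_cand <- cand[is.na(row4col[cand])]
      j <- if (length(free_cand)) free_cand[1] else cand[1]
      min_val <- lowest
      if (is.na(row4col[j])) sink <- j else i <- row4col[j]
      SC[j] <- TRUE
      remaining <- remaining[remaining != j]
    }
    u[cur_row] <- u[cur_row] + min_val
    upd_rows <- which(SR & seq_len(nr) != cur_row)
    if (length(upd_rows))
      u[upd_rows] <- u[upd_rows] + min_val - shortest[col4row[upd_rows]]
    upd_cols <- which(SC)
    v[upd_cols] <- v[upd_cols] - (min_val - shortest[upd_cols])
    # augment along the alternating path back to cur_row
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      tmp <- col4row[i]
      col4row[i] <- j
      if (i == cur_row) break
      j <- tmp
    }
  }
  col4row
}
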