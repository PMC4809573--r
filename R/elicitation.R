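#' Load matching-task responses
#'
#' Reads (or validates) a table of matching-task records: for each participant,
#' each ordered pair of temporal points `(t_i, t_j)` with `t_j > t_i`, and each
#' base amount `y_i`, the amount `y_j` the participant declared indifferent to
#' `y_i` at the earlier time. Expected columns:
#' `participant_id, base_amount, t_i, t_j, matched_amount, attention_failed`.
#'
#' Any complete design is accepted — every participant must answer every
#' `(base, pair)` cell of a common temporal grid. The five-point grids used in
#' elicitation studies (e.g. 0/12/24/60/84 or 0/1/9/18/36 months crossed with
#' $100 and $200 bases, 20 responses per participant) are the typical shape.
#'
#' @param table Path to a CSV file, or a data.frame already in memory.
#' @return A data.frame of validated responses (class `matching_responses`),
#'   ordered by participant, base, pair.
#' @export
load_responses <- function(table) {
  df <- if (is.character(table)) {
    utils::read.csv(table, stringsAsFactors = FALSE)
  } else {
    as.data.frame(table)
  }
  needed <- c("participant_id", "base_amount", "t_i", "t_j",
              "matched_amount", "attention_failed")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("load_responses: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[needed]
  df$attention_failed <- as.logical(df$attention_failed)
  if (any(df$base_amount <= 0) || any(df$matched_amount <= 0)) {
    stop("validation error: amounts must be positive")
  }
  if (any(df$t_j <= df$t_i)) {
    stop("validation error: t_j must exceed t_i in every record")
  }
  grid <- sort(unique(c(df$t_i, df$t_j)))
  n <- length(grid)
  bases <- sort(unique(df$base_amount))
  pairs <- t(utils::combn(grid, 2))
  want <- nrow(pairs) * length(bases)
  for (id in unique(df$participant_id)) {
    rows <- df[df$participant_id == id, ]
    key <- unique(paste(rows$base_amount, rows$t_i, rows$t_j))
    full <- as.vector(outer(bases, paste(pairs[, 1], pairs[, 2]), paste))
    if (!setequal(key, full) || nrow(rows) != want) {
      stop(sprintf(
        "incomplete design: participant %s does not cover all %d (base, pair) cells",
        id, want))
    }
  }
  df <- df[order(df$participant_id, df$base_amount, df$t_i, df$t_j), ]
  rownames(df) <- NULL
  attr(df, "time_grid") <- grid
  attr(df, "base_amounts") <- bases
  class(df) <- c("matching_responses", "data.frame")
  df
}

# Count monotonicity violations for one participant's rows: an instance of
# preferring a smaller, later reward. Either the matched amount fails to
# exceed the base (y_j <= y_i with t_j > t_i), or, at the same base and same
# earlier time, the matched amount fails to increase as the horizon grows.
count_violations <- function(rows) {
  v <- sum(rows$matched_amount <= rows$base_amount)
  for (b in unique(rows$base_amount)) {
    for (ti in unique(rows$t_i[rows$base_amount == b])) {
      sub <- rows[rows$base_amount == b & rows$t_i == ti, ]
      sub <- sub[order(sub$t_j), ]
      if (nrow(sub) > 1) v <- v + sum(diff(sub$matched_amount) <= 0)
    }
  }
  v
}

#' Apply the participant exclusion rules
#'
#' Drops (a) participants flagged by the attention check and (b) participants
#' with more than one instance of preferring a smaller, later reward (see
#' [count_violations] in the source: a matched amount not exceeding its base,
#' or matched amounts non-increasing across growing horizons at the same base
#' and start time). A single violation is tolerated and the offending
#' response is kept — people are excluded, not rows.
#'
#' @param responses A `matching_responses` table from [load_responses()].
#' @return A list with `retained` (a `matching_responses` table) and
#'   `excluded`, a data.frame of participant ids with the reason and
#'   violation count.
#' @export
apply_exclusions <- function(responses) {
  stopifnot(inherits(responses, "matching_responses"))
  ids <- unique(responses$participant_id)
  reasons <- lapply(ids, function(id) {
    rows <- responses[responses$participant_id == id, ]
    nv <- count_violations(rows)
    if (any(rows$attention_failed)) {
      data.frame(participant_id = id, reason = "attention_check",
                 violations = nv)
    } else if (nv > 1) {
      data.frame(participant_id = id, reason = "monotonicity_violations",
                 violations = nv)
    } else {
      NULL
    }
  })
  excluded <- do.call(rbind, reasons)
  if (is.null(excluded)) {
    excluded <- data.frame(participant_id = character(0),
                           reason = character(0), violations = integer(0))
  }
  keep <- !(responses$participant_id %in% excluded$participant_id)
  retained <- responses[keep, ]
  for (a in c("time_grid", "base_amounts")) {
    attr(retained, a) <- attr(responses, a)
  }
  class(retained) <- class(responses)
  list(retained = retained, excluded = excluded)
}

#' Latent distance matrix
#'
#' The `n(n-1)/2` pairwise decision-space distances inferred for one
#' participant over an `n`-point temporal grid. Stored as a full symmetric
#' matrix with the grid (months) as labels; `n >= 4` is required downstream
#' for curvature identifiability (a 2D embedding plus a curvature needs at
#' least 6 observed distances).
#'
#' @param labels Numeric temporal grid (months), length n.
#' @param d Either an n x n symmetric matrix or the upper-triangle vector in
#'   row-major (combn) order.
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(labels, d) {
  n <- length(labels)
  if (is.matrix(d)) {
    stopifnot(nrow(d) == n, ncol(d) == n)
    m <- d
  } else {
    stopifnot(length(d) == n * (n - 1) / 2)
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- d  # combn order fills by column = lower triangle
    m <- m + t(m)
  }
  if (any(m < 0)) stop("distance_matrix: distances must be >= 0")
  dimnames(m) <- list(labels, labels)
  structure(list(labels = as.numeric(labels), d = m),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d temporal points (months: %s)\n",
              length(x$labels), paste(x$labels, collapse = ", ")))
  print(signif(x$d, 4))
  invisible(x)
}

# Upper-triangle vector of a distance_matrix, in combn (column-major) order.
upper_tri <- function(D) {
  stopifnot(inherits(D, "distance_matrix"))
  D$d[lower.tri(D$d)]
}

#' Infer decision-space distances from matching responses
#'
#' For each temporal pair, the indifference condition
#' `y_i = y_j * exp(-d_ij)` inverts to `d_ij = log(y_j / y_i)`; the ratio is
#' first averaged across the base amounts (mean of ratios, then log) to damp
#' outlier responses. A power money-perception exponent `alpha` scales every
#' distance linearly: `d_ij(alpha) = alpha * d_ij(1)`, which is why
#' classification downstream is alpha-stable.
#'
#' Ratios at or below 1 would give non-positive distances; they are floored
#' at 0 with a warning (the embedding algorithms require non-negative input).
#'
#' @param responses A `matching_responses` table for ONE participant.
#' @param alpha Money-perception exponent (default 1, linear).
#' @return A `distance_matrix` over the participant's temporal grid.
#' @export
distances_from_matching <- function(responses, alpha = 1) {
  stopifnot(inherits(responses, "matching_responses"),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  if (length(unique(responses$participant_id)) != 1L) {
    stop("distances_from_matching: expects a single participant; ",
         "use participant_distances() for a cohort")
  }
  grid <- sort(unique(c(responses$t_i, responses$t_j)))
  n <- length(grid)
  if (n < 4) stop("under-identified: need at least 4 temporal points")
  pairs <- t(utils::combn(grid, 2))
  d <- apply(pairs, 1, function(pr) {
    rows <- responses[responses$t_i == pr[1] & responses$t_j == pr[2], ]
    ratio <- mean(rows$matched_amount / rows$base_amount)
    alpha * log(ratio)
  })
  if (any(d < 0)) {
    warning(sprintf(
      "%d pair(s) with matched/base ratio <= 1; distance floored at 0",
      sum(d < 0)))
    d <- pmax(d, 0)
  }
  distance_matrix(grid, d)
}

#' Distance matrices for every retained participant
#'
#' @param responses A `matching_responses` table (any number of participants).
#' @param alpha Money-perception exponent.
#' @return Named list of `distance_matrix` objects, one per participant.
#' @export
participant_distances <- function(responses, alpha = 1) {
  ids <- unique(responses$participant_id)
  out <- lapply(ids, function(id) {
    rows <- responses[responses$participant_id == id, ]
    for (a in c("time_grid", "base_amounts")) {
      attr(rows, a) <- attr(responses, a)
    }
    class(rows) <- class(responses)
    distances_from_matching(rows, alpha = alpha)
  })
  stats::setNames(out, ids)
}

#' Serialize / deserialize a distance matrix as JSON
#'
#' The JSON form carries the temporal labels and the upper-triangle vector in
#' column-major pair order.
#'
#' @param D A `distance_matrix`.
#' @param path File to write; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_distance_matrix <- function(D, path = NULL) {
  stopifnot(inherits(D, "distance_matrix"))
  obj <- list(labels = D$labels, d = upper_tri(D))
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param json Path to a JSON file or a JSON string.
#' @export
read_distance_matrix <- function(json) {
  obj <- jsonlite::fromJSON(json)
  distance_matrix(obj$labels, obj$d)
}
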