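#' Heterotic-group assignment thresholds
#'
#' `q_major` is the dominant-ancestry cut, `delta_clear` the margin over
#' the runner-up needed for a clear assignment, and `delta_para` the margin
#' that still earns a Para (peripheral) label when the top Q is not
#' dominant. Defaults are the published rule values.
#'
#' @param q_major Dominance threshold on the top Q (default 0.5).
#' @param delta_clear Top-minus-second margin for a clear call (default 0.1).
#' @param delta_para Margin for a Para call at non-dominant top Q
#'   (default 0.15).
#' @return An `assignment_thresholds` list.
#' @export
assignment_thresholds <- function(q_major = 0.5, delta_clear = 0.1,
                                  delta_para = 0.15) {
  t <- list(q_major = q_major, delta_clear = delta_clear,
            delta_para = delta_para)
  if (any(unlist(t) <= 0) || any(unlist(t) >= 1))
    stop("assignment thresholds must lie in (0, 1)")
  class(t) <- "assignment_thresholds"
  t
}

#' Default group identity: argmax of the Q row
#'
#' Ties are broken by group order (first listed wins) and flagged.
#'
#' @param q Numeric Q row (proportions summing to 1).
#' @param groups Group labels (default names of `q` or G1..GK).
#' @return Character label; attribute `tie` is `TRUE` when the maximum is
#'   shared.
#' @export
default_id <- function(q, groups = NULL) {
  groups <- groups %||% names(q) %||% sprintf("G%d", seq_along(q))
  i <- which.max(q)
  structure(groups[i], tie = sum(q == q[i]) > 1L)
}

#' Adjusted group identity (Group / Group_Para / Mixed)
#'
#' With A the group of the largest Q value and B the runner-up:
#' assign `A` when Q_A > 0.5 and Q_A - Q_B > 0.1; assign `A_Para` when
#' Q_A > 0.5 and Q_A - Q_B < 0.1, or when Q_A <= 0.5 and Q_A - Q_B >= 0.15;
#' otherwise assign `Mixed`. The margin exactly equal to `delta_clear`
#' (covered by neither strict inequality of the published rule) resolves to
#' the clear assignment `A` and is flagged as a boundary case.
#'
#' @param q Numeric Q row.
#' @param thresholds An [assignment_thresholds()].
#' @param groups Group labels.
#' @return Character label (`"<A>"`, `"<A>_Para"` or `"Mixed"`); attribute
#'   `boundary` marks the exact-margin case.
#' @export
adjusted_id <- function(q, thresholds = assignment_thresholds(),
                        groups = NULL) {
  groups <- groups %||% names(q) %||% sprintf("G%d", seq_along(q))
  ord <- order(q, decreasing = TRUE)
  qa <- unname(q[ord[1]])
  qb <- if (length(q) > 1) unname(q[ord[2]]) else 0
  a <- groups[ord[1]]
  d <- qa - qb
  boundary <- qa > thresholds$q_major &&
    isTRUE(all.equal(d, thresholds$delta_clear))
  lab <- if (qa > thresholds$q_major &&
             (d > thresholds$delta_clear || boundary)) a
  else if ((qa > thresholds$q_major && d < thresholds$delta_clear) ||
           (qa <= thresholds$q_major && d >= thresholds$delta_para))
    paste0(a, "_Para")
  else "Mixed"
  structure(lab, boundary = boundary)
}

#' Assign every line from a Q matrix
#'
#' Applies [default_id()] and [adjusted_id()] row-wise.
#'
#' @param Q Lines x K admixture matrix (rownames = line names).
#' @param thresholds An [assignment_thresholds()].
#' @param groups Group labels (default column names of `Q`).
#' @return Data frame: `line`, `default_id`, `default_tie`, `adjusted_id`,
#'   `base_group` (adjusted with any `_Para` suffix stripped; `"Mixed"`
#'   kept), `q_max`, `q_second`, `group_of_max`, `group_of_second`,
#'   `boundary`.
#' @export
assign_groups <- function(Q, thresholds = assignment_thresholds(),
                          groups = NULL) {
  groups <- groups %||% colnames(Q) %||% sprintf("G%d", seq_len(ncol(Q)))
  rows <- lapply(seq_len(nrow(Q)), function(i) {
    q <- Q[i, ]
    d <- default_id(q, groups)
    a <- adjusted_id(q, thresholds, groups)
    ord <- order(q, decreasing = TRUE)
    data.frame(line = rownames(Q)[i] %||% as.character(i),
               default_id = as.character(d),
               default_tie = attr(d, "tie"),
               adjusted_id = as.character(a),
               base_group = sub("_Para$", "", as.character(a)),
               q_max = q[ord[1]],
               q_second = if (length(q) > 1) q[ord[2]] else 0,
               group_of_max = groups[ord[1]],
               group_of_second = if (length(q) > 1) groups[ord[2]]
               else NA_character_,
               boundary = attr(a, "boundary"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Name fitted groups after indicator lines
#'
#' Fitted admixture groups are anonymous (label switching is resolved only
#' up to an ordering); their biological names come from indicator lines of
#' independently known group identity. Each fitted column is renamed to
#' the majority `known_group` among the indicator lines whose largest Q
#' value falls in that column; columns claiming an already-taken or no
#' name keep their original label.
#'
#' @param Q Lines x K admixture matrix (rownames = line names).
#' @param registry Line registry with `line` and `known_group`.
#' @return List: `Q` (renamed columns), `names` (old -> new mapping).
#' @export
name_groups_by_indicators <- function(Q, registry) {
  known <- registry[!is.na(registry$known_group), , drop = FALSE]
  old <- colnames(Q) %||% sprintf("G%d", seq_len(ncol(Q)))
  new <- old
  idx <- match(known$line, rownames(Q))
  known <- known[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (nrow(known)) {
    top <- max.col(Q[idx, , drop = FALSE])
    cand <- vapply(seq_len(ncol(Q)), function(k) {
      votes <- known$known_group[top == k]
      if (!length(votes)) NA_character_
      else names(sort(table(votes), decreasing = TRUE))[1]
    }, "")
    ok <- !is.na(cand) & !(cand %in% cand[duplicated(cand)])
    new[ok] <- cand[ok]
    new <- make.unique(new)
  }
  colnames(Q) <- new
  list(Q = Q, names = stats::setNames(new, old))
}

#' Concordance of assignments with indicator lines
#'
#' An assignment is concordant when its adjusted identity, with any
#' `_Para` suffix stripped, equals the line's independently known group;
#' `Mixed` counts as discordant.
#'
#' @param assignments Output of [assign_groups()].
#' @param registry Line registry with columns `line` and `known_group`.
#' @return List: `fraction` concordant and `table` (per indicator line).
#' @export
indicator_concordance <- function(assignments, registry) {
  known <- registry[!is.na(registry$known_group), c("line", "known_group")]
  if (!nrow(known)) stop("no indicator lines with a known group")
  tab <- merge(known, assignments, by = "line", sort = FALSE)
  tab$concordant <- tab$base_group == tab$known_group &
    tab$adjusted_id != "Mixed"
  list(fraction = mean(tab$concordant),
       table = tab[, c("line", "known_group", "default_id", "adjusted_id",
                       "q_max", "concordant")])
}

#' Group share table
#'
#' Proportions of lines per group in two modes: `para_with_base` pools each
#' Para subgroup with its base group (Mixed kept separate);
#' `para_separate` counts every adjusted label on its own. An optional
#' grouping map rolls groups up into supergroups.
#'
#' @param assignments Output of [assign_groups()].
#' @param supergroups Optional named character vector mapping base group ->
#'   supergroup.
#' @return List of data frames (`group`, `n`, `proportion`), each summing
#'   to 1: `para_with_base`, `para_separate`, and `supergroup` when a map
#'   is given.
#' @export
group_shares <- function(assignments, supergroups = NULL) {
  n <- nrow(assignments)
  share <- function(labels) {
    tab <- table(labels)
    data.frame(group = names(tab), n = as.integer(tab),
               proportion = as.integer(tab) / n, row.names = NULL)
  }
  out <- list(para_with_base = share(assignments$base_group),
              para_separate = share(assignments$adjusted_id))
  if (!is.null(supergroups)) {
    lab <- ifelse(assignments$base_group == "Mixed", "Mixed",
                  unname(supergroups[assignments$base_group]))
    lab[is.na(lab)] <- "other"
    out$supergroup <- share(lab)
  }
  out
}
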