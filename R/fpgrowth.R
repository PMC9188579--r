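#' @title FP-growth frequent-itemset mining
#' @description
#' Mines all itemsets whose support count meets `ceiling(min_support * n)`
#' from a stratum's transactions. The implementation is the classic
#' FP-growth scheme: transactions are compressed into a frequent-pattern
#' tree (items ordered by descending support, ties broken lexicographically
#' for determinism) and the tree is mined recursively via conditional
#' pattern bases, so no candidate generation is needed. The support
#' threshold is inclusive: a pattern present in exactly `min_support * n`
#' transactions is frequent.
#'
#' @param x a [transaction_set()], or a plain list of character vectors
#'   (each a patient's deduplicated item set).
#' @param min_support minimum support fraction in (0, 1]; default 0.05.
#' @param min_size smallest itemset size reported (default 1).
#' @param max_size optional cap on itemset size (default `Inf`, no cap).
#' @param n_patients denominator override when `x` is a plain list.
#' @return data.frame with columns `items` (semicolon-joined, sorted),
#'   `size`, `support_count`, `n_patients`, `prevalence`, plus `race`,
#'   `age_band`, `obesity_class` when `x` carries a stratum. Rows are
#'   ordered by size, then lexicographically by items.
#' @examples
#' trans <- list(c("I10", "G47", "E78"), c("I10", "E78"), "G47",
#'               c("I10", "R06"), c("I10", "R06", "E78"))
#' mine_frequent_itemsets(trans, min_support = 0.6)
#' @export
mine_frequent_itemsets <- function(x, min_support = 0.05, min_size = 1L,
                                   max_size = Inf, n_patients = NULL) {
  ts <- as_transaction_list(x, n_patients)
  if (ts$n == 0L) stop("empty stratum: n_patients = 0", call. = FALSE)
  if (min_support <= 0 || min_support > 1)
    stop("min_support must be in (0, 1]", call. = FALSE)
  minc <- max(1L, as.integer(ceiling(min_support * ts$n - 1e-9)))
  pats <- fp_growth(ts$transactions, minc, max_size)
  pattern_frame(pats, ts$n, ts$stratum, min_size)
}

#' Brute-force frequent-itemset enumeration (test oracle)
#'
#' Enumerates every non-empty subset of the observed item universe and
#' counts support by containment. Exponential in the number of items, so
#' guarded to universes of at most `max_items`; intended as an independent
#' oracle for [mine_frequent_itemsets()], with the identical output
#' contract.
#'
#' @inheritParams mine_frequent_itemsets
#' @param max_items refuse universes larger than this (default 20).
#' @return same contract as [mine_frequent_itemsets()].
#' @export
brute_force_itemsets <- function(x, min_support = 0.05, min_size = 1L,
                                 max_size = Inf, n_patients = NULL,
                                 max_items = 20L) {
  ts <- as_transaction_list(x, n_patients)
  if (ts$n == 0L) stop("empty stratum: n_patients = 0", call. = FALSE)
  universe <- sort(unique(unlist(ts$transactions)))
  if (length(universe) > max_items)
    stop("item universe has ", length(universe), " items; ",
         "brute_force_itemsets is a test oracle for small universes only",
         call. = FALSE)
  minc <- max(1L, as.integer(ceiling(min_support * ts$n - 1e-9)))
  pats <- list()
  top <- min(length(universe), max_size)
  for (k in seq_len(top)) {
    if (k > length(universe)) break
    sets <- utils::combn(universe, k, simplify = FALSE)
    for (s in sets) {
      cnt <- sum(vapply(ts$transactions, function(t) all(s %in% t), logical(1)))
      if (cnt >= minc) pats[[length(pats) + 1L]] <- list(items = s, count = cnt)
    }
  }
  pattern_frame(pats, ts$n, ts$stratum, min_size)
}

#' Keep only multimorbidity patterns (two or more conditions)
#'
#' Multimorbidity is the presence of two or more chronic conditions in one
#' individual, so singleton itemsets are dropped from reporting.
#'
#' @param patterns pattern data.frame from [mine_frequent_itemsets()].
#' @return the rows with `size >= 2`.
#' @export
filter_multimorbidity <- function(patterns) {
  patterns[patterns$size >= 2L, , drop = FALSE]
}

#' Mine every stratum of a cohort
#'
#' @param transaction_sets named list from [build_transactions()].
#' @inheritParams mine_frequent_itemsets
#' @return one pattern data.frame with stratum columns, all strata stacked.
#' @export
mine_strata <- function(transaction_sets, min_support = 0.05, min_size = 1L,
                        max_size = Inf) {
  out <- lapply(transaction_sets, mine_frequent_itemsets,
                min_support = min_support, min_size = min_size,
                max_size = max_size)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- internals --------------------------------------------------------

as_transaction_list <- function(x, n_patients = NULL) {
  if (inherits(x, "transaction_set")) {
    list(transactions = unname(x$transactions), n = x$n_patients,
         stratum = x$stratum)
  } else if (is.list(x)) {
    trans <- lapply(x, function(t) unique(as.character(t)))
    list(transactions = unname(trans),
         n = as.integer(n_patients %||% length(trans)), stratum = NULL)
  } else {
    stop("x must be a transaction_set or a list of character vectors",
         call. = FALSE)
  }
}

pattern_frame <- function(pats, n, stratum, min_size) {
  if (length(pats)) {
    keys <- vapply(pats, function(p) items_key(p$items), character(1))
    size <- lengths(lapply(pats, `[[`, "items"))
    cnt <- vapply(pats, function(p) as.integer(p$count), integer(1))
    df <- data.frame(items = keys, size = as.integer(size),
                     support_count = cnt, n_patients = n,
                     prevalence = cnt / n, stringsAsFactors = FALSE)
    df <- df[df$size >= min_size, , drop = FALSE]
    df <- df[order(df$size, df$items), , drop = FALSE]
  } else {
    df <- data.frame(items = character(0), size = integer(0),
                     support_count = integer(0), n_patients = integer(0),
                     prevalence = numeric(0), stringsAsFactors = FALSE)
  }
  if (!is.null(stratum)) {
    df <- cbind(data.frame(race = rep(stratum$race, nrow(df)),
                           age_band = rep(stratum$age_band, nrow(df)),
                           obesity_class = rep(stratum$obesity_class, nrow(df)),
                           stringsAsFactors = FALSE),
                df)
  }
  rownames(df) <- NULL
  df
}

fp_node <- function(item, parent) {
  e <- new.env(parent = emptyenv())
  e$item <- item
  e$count <- 0L
  e$parent <- parent
  e$children <- new.env(parent = emptyenv())
  e
}

# transactions: list of character vectors already filtered to frequent
# items and sorted in tree order; counts: weight of each transaction
fp_build <- function(transactions, counts, items_in_order) {
  root <- fp_node(NA_character_, NULL)
  header <- new.env(parent = emptyenv())
  for (it in items_in_order) assign(it, list(), envir = header)
  for (i in seq_along(transactions)) {
    node <- root
    w <- counts[i]
    for (it in transactions[[i]]) {
      child <- get0(it, envir = node$children, inherits = FALSE)
      if (is.null(child)) {
        child <- fp_node(it, node)
        assign(it, child, envir = node$children)
        assign(it, c(get(it, envir = header), child), envir = header)
      }
      child$count <- child$count + w
      node <- child
    }
  }
  list(root = root, header = header)
}

# recursive FP-growth over weighted transactions; returns list of
# list(items = character vector, count = integer)
fp_growth <- function(transactions, minc, max_size = Inf,
                      suffix = character(0), counts = NULL) {
  if (is.null(counts)) counts <- rep(1L, length(transactions))
  if (length(suffix) >= max_size) return(list())
  supp <- item_support(transactions, counts)
  supp <- supp[supp >= minc]
  if (!length(supp)) return(list())
  # descending support, lexicographic tie-break: deterministic tree order
  ord <- order(-supp, names(supp))
  items <- names(supp)[ord]
  rank <- stats::setNames(seq_along(items), items)
  proj <- lapply(transactions, function(t) {
    t <- t[t %in% items]
    t[order(rank[t])]
  })
  keep <- lengths(proj) > 0L
  tree <- fp_build(proj[keep], counts[keep], items)

  out <- vector("list", 0L)
  for (it in rev(items)) {            # least-frequent first, standard order
    nodes <- get(it, envir = tree$header)
    pattern <- c(it, suffix)
    out[[length(out) + 1L]] <- list(items = pattern,
                                    count = as.integer(supp[[it]]))
    if (length(pattern) >= max_size) next
    # conditional pattern base: prefix path of every node carrying `it`
    cond_trans <- list(); cond_counts <- integer(0)
    for (nd in nodes) {
      path <- character(0)
      p <- nd$parent
      while (!is.null(p) && !is.na(p$item)) {
        path <- c(p$item, path)
        p <- p$parent
      }
      if (length(path)) {
        cond_trans[[length(cond_trans) + 1L]] <- path
        cond_counts <- c(cond_counts, nd$count)
      }
    }
    if (length(cond_trans)) {
      out <- c(out, fp_growth(cond_trans, minc, max_size,
                              suffix = pattern, counts = cond_counts))
    }
  }
  out
}

item_support <- function(transactions, counts) {
  if (!length(transactions)) return(stats::setNames(integer(0), character(0)))
  items <- unlist(transactions, use.names = FALSE)
  w <- rep(counts, lengths(transactions))
  v <- tapply(w, items, sum)
  stats::setNames(as.integer(v), names(v))
}
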