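# Step 4: minimum set cover over the gRNA-target coverage map.
# Two solvers: greedy list-and-remove (prioritising 5'-proximal gRNA) and
# an exact enumerator (seeded greedy bound + branch-and-bound search) that
# can rank minimum covers by non-redundancy.

#' Build the coverage map from a mapping table
#'
#' Rows with any `fail` verdict are excluded; `NA` verdicts count as pass.
#' The universe is the full set of target ids present in the table, so
#' targets left with no covering gRNA are reported as uncovered.
#'
#' @param mapping `grna_mapping` from [apply_filters()] or
#'   [read_mapping()] (possibly edited externally).
#' @return object of class `coverage_map`: `universe` (target ids),
#'   `sets` (named list gRNA id -> covered target ids), `pos5` (named list
#'   gRNA id -> named integer vector of minimum hit start per target),
#'   `spacers` (gRNA id -> sequence), `uncovered`.
#' @export
build_coverage <- function(mapping) {
  if (nrow(mapping) == 0L) stop("empty mapping table")
  checks <- grep("^check:", names(mapping), value = TRUE)
  pass <- rep(TRUE, nrow(mapping))
  for (cc in checks) {
    v <- mapping[[cc]]
    pass <- pass & (is.na(v) | v %in% c("pass", "NA"))
  }
  universe <- sort(unique(mapping$target_id))
  ok <- mapping[pass, , drop = FALSE]
  sets <- lapply(split(ok$target_id, ok$grna_id), function(x) sort(unique(x)))
  sets <- sets[lengths(sets) > 0L]
  pos5 <- lapply(split(ok[, c("target_id", "start")], ok$grna_id),
                 function(df) vapply(split(df$start, df$target_id), min,
                                     double(1)))
  pos5 <- pos5[names(sets)]
  spacers <- setNames(mapping$grna_seq, mapping$grna_id)
  spacers <- spacers[!duplicated(names(spacers))]
  covered <- sort(unique(unlist(sets, use.names = FALSE)))
  structure(list(universe = universe, sets = sets, pos5 = pos5,
                 spacers = spacers,
                 uncovered = setdiff(universe, covered)),
            class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf("<coverage_map> %d target(s), %d gRNA with coverage; %d uncovered\n",
              length(x$universe), length(x$sets), length(x$uncovered)))
  invisible(x)
}

new_cover_solution <- function(grna_ids, algorithm, priority, covered,
                               uncovered = character(0)) {
  structure(list(grna_ids = grna_ids, algorithm = algorithm,
                 priority = priority, covered = covered,
                 uncovered = uncovered,
                 partial = length(uncovered) > 0L),
            class = "cover_solution")
}

#' @export
print.cover_solution <- function(x, ...) {
  cat(sprintf("<cover_solution> [%s/%s] %d gRNA covering %d target(s)%s\n",
              x$algorithm, x$priority, length(x$grna_ids),
              length(x$covered),
              if (x$partial) sprintf(" (PARTIAL: %d uncovered)",
                                     length(x$uncovered)) else ""))
  invisible(x)
}

# minimum pos5 of a gRNA over a set of targets (Inf if none recorded)
min_pos5 <- function(cov, g, targets) {
  p <- cov$pos5[[g]]
  p <- p[names(p) %in% targets]
  if (!length(p)) Inf else min(p)
}

#' Greedy list-and-remove cover prioritising 5'-proximity
#'
#' Repeatedly selects the gRNA covering the most uncovered targets,
#' breaking ties by the smallest minimum hit distance from the target 5'
#' end over its uncovered targets, then by lexicographic gRNA id; covered
#' targets are removed until the universe is exhausted.  If the universe
#' cannot be covered the partial solution is returned together with the
#' explicit uncovered list.
#'
#' @param cov `coverage_map` from [build_coverage()].
#' @param pool optional character vector restricting the usable gRNA.
#' @return `cover_solution`.
#' @export
lar_cover <- function(cov, pool = NULL) {
  pool <- pool %||% names(cov$sets)
  uncovered <- cov$universe
  chosen <- character(0)
  while (length(uncovered) > 0L) {
    gains <- vapply(pool, function(g)
      length(intersect(cov$sets[[g]], uncovered)), integer(1))
    if (!length(gains) || max(gains) == 0L) break
    best <- pool[gains == max(gains)]
    if (length(best) > 1L) {
      p5 <- vapply(best, function(g)
        min_pos5(cov, g, intersect(cov$sets[[g]], uncovered)), double(1))
      best <- best[p5 == min(p5)]
    }
    pick <- sort(best)[1L]
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, cov$sets[[pick]])
    pool <- setdiff(pool, pick)
  }
  new_cover_solution(chosen, "LAR", "pos5",
                     setdiff(cov$universe, uncovered), uncovered)
}

# greedy completion of a partial cover under a random tie-break
greedy_complete <- function(cov, pool, start_with) {
  chosen <- start_with
  uncovered <- setdiff(cov$universe,
                       unique(unlist(cov$sets[chosen], use.names = FALSE)))
  pool <- setdiff(pool, chosen)
  while (length(uncovered) > 0L) {
    gains <- vapply(pool, function(g)
      length(intersect(cov$sets[[g]], uncovered)), integer(1))
    if (!length(gains) || max(gains) == 0L) return(NULL)
    best <- pool[gains == max(gains)]
    pick <- if (length(best) == 1L) best else sample(best, 1L)
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, cov$sets[[pick]])
    pool <- setdiff(pool, pick)
  }
  chosen
}

redundancy <- function(cov, grna_ids) {
  sum(lengths(cov$sets[grna_ids])) - length(cov$universe)
}

solution_pos5_score <- function(cov, grna_ids) {
  sum(vapply(grna_ids, function(g) min_pos5(cov, g, cov$sets[[g]]),
             double(1)))
}

#' Enumerate minimum gRNA covers
#'
#' Phase 1 estimates an upper bound on the cover size by greedy completion
#' seeded with each gRNA as forced first member under `seed_iterations`
#' random tie-break draws; phase 2 runs an exhaustive branch-and-bound
#' over covers within that bound (branching on the uncovered target with
#' the fewest covering gRNA) and returns every minimum-size cover, ranked
#' by the requested priority: `"nonredundant"` minimises total redundant
#' coverings `sum(|coverage|) - |universe|`, `"pos5"` minimises the summed
#' 5'-proximity of the members; ties break lexicographically.
#'
#' @param cov `coverage_map`.
#' @param n_solutions maximum number of covers to return (`Inf` = all).
#' @param seed_iterations greedy randomisation draws per seed gRNA.
#' @param priority `"nonredundant"` or `"pos5"`.
#' @param pool optional restriction of usable gRNA.
#' @param max_nodes branch-and-bound node budget; on overflow the best
#'   covers found so far are returned with a warning that the bound is
#'   not proven optimal.
#' @return list of `cover_solution` objects (empty if nothing covers).
#' @export
enumerate_min_covers <- function(cov, n_solutions = Inf,
                                 seed_iterations = 100L,
                                 priority = c("nonredundant", "pos5"),
                                 pool = NULL, max_nodes = 1e7) {
  priority <- match.arg(priority)
  pool <- pool %||% names(cov$sets)
  coverable <- sort(unique(unlist(cov$sets[pool], use.names = FALSE)))
  target_universe <- intersect(cov$universe, coverable)
  uncoverable <- setdiff(cov$universe, coverable)
  if (!length(pool) || !length(target_universe)) return(list())

  # phase 1: seeded greedy upper bound
  kstar <- Inf
  for (g in pool) {
    for (it in seq_len(seed_iterations)) {
      sol <- greedy_complete(
        structure(list(universe = target_universe, sets = cov$sets,
                       pos5 = cov$pos5), class = "coverage_map"),
        pool, g)
      if (!is.null(sol)) kstar <- min(kstar, length(sol))
    }
  }
  if (!is.finite(kstar)) return(list())

  # phase 2: branch and bound for all covers of minimum size <= kstar
  sets <- cov$sets[pool]
  best_k <- kstar
  found <- list()
  nodes <- 0L
  overflow <- FALSE
  recurse <- function(chosen, uncovered, candidates) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) { overflow <<- TRUE; return() }
    if (!length(uncovered)) {
      k <- length(chosen)
      if (k < best_k) { best_k <<- k; found <<- list() }
      if (k == best_k)
        found[[length(found) + 1L]] <<- sort(chosen)
      return()
    }
    if (length(chosen) >= best_k) return()
    counts <- vapply(candidates, function(g)
      length(intersect(sets[[g]], uncovered)), integer(1))
    candidates <- candidates[counts > 0L]
    counts <- counts[counts > 0L]
    if (!length(candidates)) return()
    # simple lower bound: remaining targets / best gain
    if (length(chosen) + ceiling(length(uncovered) / max(counts)) > best_k)
      return()
    # branch on the uncovered target with fewest covering candidates
    covering <- lapply(uncovered, function(t)
      candidates[vapply(candidates, function(g) t %in% sets[[g]],
                        logical(1))])
    pick <- which.min(lengths(covering))
    for (g in covering[[pick]]) {
      recurse(c(chosen, g), setdiff(uncovered, sets[[g]]),
              setdiff(candidates, g))
    }
  }
  recurse(character(0), target_universe, pool)
  if (overflow)
    warning("branch-and-bound node budget exhausted; ",
            "minimum cover size not proven optimal")
  if (!length(found)) return(list())
  found <- unique(found)
  ord <- order(
    if (priority == "nonredundant")
      vapply(found, function(s) redundancy(cov, s), double(1))
    else vapply(found, function(s) solution_pos5_score(cov, s), double(1)),
    vapply(found, paste, character(1), collapse = ","))
  found <- found[ord]
  if (is.finite(n_solutions)) found <- head(found, n_solutions)
  lapply(found, function(s)
    new_cover_solution(s, "enumerate", priority, target_universe,
                       uncoverable))
}

#' Mutually exclusive gRNA cover sets
#'
#' Computes `n_sets` covers sequentially; gRNA used by earlier sets are
#' removed from the pool before the next set is computed.  A later set
#' that can no longer cover the full universe is returned as an explicit
#' partial solution, never silently dropped.
#'
#' @param cov `coverage_map`.
#' @param n_sets number of mutually exclusive sets requested.
#' @param priority `"pos5"` (greedy list-and-remove) or `"nonredundant"`
#'   (exact enumeration ranked by non-redundancy).
#' @param seed_iterations,max_nodes passed to [enumerate_min_covers()].
#' @return list of `cover_solution` objects, length `n_sets`.
#' @export
mutually_exclusive_sets <- function(cov, n_sets = 1L,
                                    priority = c("pos5", "nonredundant"),
                                    seed_iterations = 100L,
                                    max_nodes = 1e7) {
  priority <- match.arg(priority)
  stopifnot(n_sets >= 1L)
  pool <- names(cov$sets)
  out <- list()
  for (i in seq_len(n_sets)) {
    if (priority == "pos5") {
      sub <- cov
      sub$sets <- cov$sets[intersect(names(cov$sets), pool)]
      sol <- lar_cover(sub, pool = pool)
    } else {
      sols <- enumerate_min_covers(cov, n_solutions = 1L,
                                   seed_iterations = seed_iterations,
                                   priority = "nonredundant", pool = pool,
                                   max_nodes = max_nodes)
      sol <- if (length(sols)) sols[[1L]] else {
        # fall back to a partial greedy cover so the shortfall is explicit
        sub <- cov
        sub$sets <- cov$sets[intersect(names(cov$sets), pool)]
        lar_cover(sub, pool = pool)
      }
    }
    out[[i]] <- sol
    pool <- setdiff(pool, sol$grna_ids)
  }
  out
}

#' Group gRNA into equivalence classes of identical coverage
#'
#' gRNA that cover exactly the same targets are interchangeable in a
#' cover; members are ordered by 5'-proximity (minimum hit offset over
#' covered targets) then id.
#'
#' @param cov `coverage_map`.
#' @return list of classes, each `list(coverage =, members =)`.
#' @export
equivalence_classes <- function(cov) {
  if (!length(cov$sets)) return(list())
  sig <- vapply(cov$sets, paste, character(1), collapse = "\r")
  groups <- split(names(cov$sets), sig)
  out <- lapply(groups, function(members) {
    coverage <- cov$sets[[members[1L]]]
    p5 <- vapply(members, function(g) min_pos5(cov, g, coverage), double(1))
    list(coverage = coverage,
         members = members[order(p5, members)])
  })
  names(out) <- NULL
  # stable order: by decreasing coverage size then first member id
  out[order(-lengths(lapply(out, `[[`, "coverage")),
            vapply(out, function(x) x$members[1L], character(1)))]
}
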