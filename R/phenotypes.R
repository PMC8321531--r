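#' Phenotype severity classes
#'
#' Mutant phenotypes are recorded on an ordinal five-class scale:
#' 0 (no abnormal phenotype), 1A (conditional), 1B (cellular/biochemical),
#' 1C (morphological) and 2 (lethal). Severity increases strictly along
#' this order.
#'
#' @return character vector of the five class codes, in increasing severity.
#' @export
phenotype_classes <- function() c("0", "1A", "1B", "1C", "2")

#' Map phenotype class codes to integer severity ranks
#'
#' @param code character vector of class codes in
#'   `{"0","1A","1B","1C","2"}`.
#' @param ranks optional named integer vector overriding the default rank
#'   map (must be a bijection onto 0..4 preserving the class order).
#' @return integer severity ranks (0 to 4).
#' @export
#' @examples
#' severity_rank(c("0", "1B", "2"))
severity_rank <- function(code, ranks = NULL) {
  if (is.null(ranks)) {
    ranks <- stats::setNames(0:4, phenotype_classes())
  } else {
    if (!setequal(names(ranks), phenotype_classes()) ||
        !identical(sort(unname(as.integer(ranks))), 0:4) ||
        is.unsorted(as.integer(ranks[phenotype_classes()]), strictly = TRUE)) {
      stop("`ranks` must map the five classes onto 0..4, increasing along 0 < 1A < 1B < 1C < 2")
    }
  }
  code <- as.character(code)
  bad <- setdiff(unique(code[!is.na(code)]), names(ranks))
  if (length(bad) > 0 || anyNA(code)) {
    stop("unknown phenotype class code(s): ",
         paste(c(bad, if (anyNA(code)) "NA"), collapse = ", "))
  }
  unname(as.integer(ranks[code]))
}

#' Default redundancy-definition rule table
#'
#' Each redundancy definition (RD1..RD9) is a predicate over the maximum
#' single-mutant severity rank and the double-mutant rank, represented as an
#' enumeration of allowed `(max_sm_rank, dm_rank)` cells:
#'
#' * RD1-RD4 ("classic" singletons): both single mutants class 0, double
#'   mutant class 1A, 1B, 1C or 2 respectively. RD5 (classic redundancy)
#'   is their union.
#' * RD6-RD8 ("subtle" redundancy): at least one single mutant abnormal,
#'   both single-mutant ranks strictly below the double-mutant rank, keyed
#'   by double-mutant class 1B, 1C and 2 respectively.
#' * RD9 (inclusive redundancy) is the union of RD1-RD8: the double mutant
#'   is strictly more severe than both single mutants.
#'
#' Nonredundancy (NR) is the complement: at least one single mutant is as
#' severe as, or more severe than, the double mutant.
#'
#' The table is plain data; supply your own to [label_trios()] to change
#' the cell assignment (it is validated against the partition invariants).
#'
#' @return data.frame with columns `definition`, `max_sm_rank`, `dm_rank`
#'   and a `provenance` attribute (`"default"`).
#' @export
default_rule_table <- function() {
  cells <- rbind(
    data.frame(definition = "RD1", max_sm_rank = 0L, dm_rank = 1L),
    data.frame(definition = "RD2", max_sm_rank = 0L, dm_rank = 2L),
    data.frame(definition = "RD3", max_sm_rank = 0L, dm_rank = 3L),
    data.frame(definition = "RD4", max_sm_rank = 0L, dm_rank = 4L),
    data.frame(definition = "RD6", max_sm_rank = 1L, dm_rank = 2L),
    data.frame(definition = "RD7", max_sm_rank = 1:2, dm_rank = 3L),
    data.frame(definition = "RD8", max_sm_rank = 1:3, dm_rank = 4L)
  )
  rd5 <- cells[cells$definition %in% paste0("RD", 1:4), -1, drop = FALSE]
  rd9 <- cells[, -1, drop = FALSE]
  out <- rbind(
    cells,
    data.frame(definition = "RD5", rd5),
    data.frame(definition = "RD9", rd9)
  )
  rownames(out) <- NULL
  attr(out, "provenance") <- "default"
  out
}

#' Validate a redundancy rule table
#'
#' Checks the structural invariants a rule table must satisfy: every cell
#' lies in the redundant half-space (`dm_rank > max_sm_rank`), RD5 equals
#' the union of RD1-RD4, RD9 equals the union of RD1-RD8, and RD9 covers
#' exactly the redundant half-space so that RD9 and NR partition all trios.
#'
#' @param rules a rule table as returned by [default_rule_table()].
#' @return the rule table, invisibly; errors on violation.
#' @export
validate_rule_table <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("definition", "max_sm_rank", "dm_rank") %in% names(rules)))
  key <- function(df) sort(paste(df$max_sm_rank, df$dm_rank))
  cell <- function(def) unique(rules[rules$definition == def, c("max_sm_rank", "dm_rank")])
  if (any(rules$dm_rank <= rules$max_sm_rank)) {
    stop("rule table places cells with dm_rank <= max_sm_rank inside a redundancy definition")
  }
  rd14 <- unique(do.call(rbind, lapply(paste0("RD", 1:4), cell)))
  if (!identical(key(cell("RD5")), key(rd14))) {
    stop("rule table invariant violated: RD5 must equal the union of RD1-RD4")
  }
  rd18 <- unique(do.call(rbind, lapply(paste0("RD", c(1:4, 6:8)), cell)))
  if (!identical(key(cell("RD9")), key(rd18))) {
    stop("rule table invariant violated: RD9 must equal the union of RD1-RD8")
  }
  full <- expand.grid(max_sm_rank = 0:4, dm_rank = 0:4)
  redundant_half <- full[full$dm_rank > full$max_sm_rank, ]
  if (!identical(key(cell("RD9")), key(redundant_half))) {
    stop("rule table invariant violated: RD9 and NR must partition all trios")
  }
  invisible(rules)
}

#' Read a mutant-trio table
#'
#' Expects a tab-separated file with header columns `pair_id`, `gene_a`,
#' `gene_b`, `sm_a_class`, `sm_b_class`, `dm_class`; phenotype classes are
#' the literal tokens 0/1A/1B/1C/2. Duplicate pair ids and self pairs are
#' rejected at load time.
#'
#' @param path path to the TSV file.
#' @return validated data.frame of trios.
#' @export
read_trios <- function(path) {
  tr <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  validate_trios(tr)
}

#' Validate a mutant-trio table
#'
#' @param trios data.frame with the columns described in [read_trios()].
#' @return the validated data.frame (phenotype columns as character).
#' @export
validate_trios <- function(trios) {
  need <- c("pair_id", "gene_a", "gene_b", "sm_a_class", "sm_b_class", "dm_class")
  miss <- setdiff(need, names(trios))
  if (length(miss) > 0) {
    stop("trio table is missing column(s): ", paste(miss, collapse = ", "))
  }
  dup <- trios$pair_id[duplicated(trios$pair_id)]
  if (length(dup) > 0) {
    stop("duplicate pair_id(s) in trio table: ", paste(unique(dup), collapse = ", "))
  }
  if (any(trios$gene_a == trios$gene_b)) {
    stop("trio table contains self pairs (gene_a == gene_b)")
  }
  for (col in c("sm_a_class", "sm_b_class", "dm_class")) {
    severity_rank(trios[[col]])  # errors on unknown tokens or NA
  }
  trios
}

#' Label a single mutant trio under the redundancy definitions
#'
#' @param sm_a,sm_b phenotype class codes of the two single mutants.
#' @param dm phenotype class code of the double mutant.
#' @param rules rule table (defaults to [default_rule_table()]).
#' @return character vector of applicable definitions: the matching RD1-RD8
#'   flags plus exactly one of `"RD9"` or `"NR"`.
#' @export
#' @examples
#' label_trio("0", "0", "2")   # extreme redundancy
#' label_trio("1C", "0", "1A") # nonredundant
label_trio <- function(sm_a, sm_b, dm, rules = default_rule_table()) {
  validate_rule_table(rules)
  m <- max(severity_rank(sm_a), severity_rank(sm_b))
  d <- severity_rank(dm)
  if (d <= m) return("NR")
  hit <- rules$definition[rules$max_sm_rank == m & rules$dm_rank == d]
  defs <- paste0("RD", 1:9)
  defs[defs %in% hit]
}

#' Label a table of mutant trios
#'
#' Adds one logical column per definition RD1..RD9 and NR. The trio is
#' treated as an unordered pair: predicates depend only on the maximum
#' single-mutant rank, so swapping `sm_a`/`sm_b` cannot change any label.
#' Every trio receives exactly one of RD9 (double mutant strictly more
#' severe than both single mutants) or NR.
#'
#' @param trios trio table (see [read_trios()]).
#' @param rules rule table (defaults to [default_rule_table()]).
#' @return the trio table with added logical label columns; class
#'   `labeled_trios`.
#' @export
label_trios <- function(trios, rules = default_rule_table()) {
  trios <- validate_trios(trios)
  validate_rule_table(rules)
  m <- pmax(severity_rank(trios$sm_a_class), severity_rank(trios$sm_b_class))
  d <- severity_rank(trios$dm_class)
  cellkey <- paste(m, d)
  for (def in paste0("RD", 1:9)) {
    cells <- rules[rules$definition == def, ]
    trios[[def]] <- cellkey %in% paste(cells$max_sm_rank, cells$dm_rank)
  }
  trios$NR <- d <= m
  stopifnot(all(xor(trios$RD9, trios$NR)))
  class(trios) <- c("labeled_trios", class(trios))
  trios
}

#' Count gene pairs per redundancy definition
#'
#' @param labeled a labeled trio table from [label_trios()].
#' @return data.frame with one row per definition (RD1..RD9, NR) and its
#'   count of gene pairs.
#' @export
count_by_definition <- function(labeled) {
  defs <- c(paste0("RD", 1:9), "NR")
  stopifnot(all(defs %in% names(labeled)))
  n <- vapply(defs, function(d) sum(labeled[[d]]), integer(1))
  stopifnot(n[["RD9"]] + n[["NR"]] == nrow(labeled))
  data.frame(definition = defs, n_pairs = unname(n))
}
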