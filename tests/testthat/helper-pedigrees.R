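# builders and brute-force oracles shared by the tests

mk_ped <- function(...) as_pedigree(data.frame(..., stringsAsFactors = FALSE))

# three generations: grandparents, father + affected uncle, proband + sib
three_gen_ped <- function() {
  mk_ped(
    family = "F1",
    id     = c("gf", "gm", "fa", "un", "mo", "pr", "sib"),
    father = c(NA, NA, "gf", "gf", NA, "fa", "fa"),
    mother = c(NA, NA, "gm", "gm", NA, "mo", "mo"),
    sex    = c("male", "female", "male", "male", "female", "male", "female"),
    affected = c("unaffected", "unaffected", "unaffected", "affected",
                 "unaffected", "affected", "affected")
  )
}

trio_ped <- function() {
  mk_ped(family = "F1", id = c("fa", "mo", "ch"),
         father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
         sex = c("male", "female", "male"),
         affected = c("unaffected", "unaffected", "affected"))
}

# random pedigree: sequential individuals take random earlier parents
random_pedigree <- function(seed, n, p_founder = 0.35, aff_rate = 0.4) {
  set.seed(seed)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  ids <- sprintf("P%03d", seq_len(n))
  father <- mother <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 4 && runif(1) > p_founder) {
      males <- which(sex[seq_len(i - 1)] == "male")
      females <- which(sex[seq_len(i - 1)] == "female")
      if (length(males) && length(females)) {
        father[i] <- ids[males[sample.int(length(males), 1)]]
        mother[i] <- ids[females[sample.int(length(females), 1)]]
      }
    }
  }
  affected <- ifelse(runif(n) < aff_rate, "affected", "unaffected")
  mk_ped(family = "F1", id = ids, father = father, mother = mother,
         sex = sex, affected = affected)
}

# brute force: all simple up-then-down paths between a and b
oracle_paths <- function(ped, a, b, max_len = 12L) {
  parent_of <- function(x, y) {  # is y a parent of x?
    i <- match(x, ped$id)
    isTRUE(ped$father[i] == y) || isTRUE(ped$mother[i] == y)
  }
  nbrs <- function(x) {
    i <- match(x, ped$id)
    kids <- ped$id[(!is.na(ped$father) & ped$father == x) |
                     (!is.na(ped$mother) & ped$mother == x)]
    c(ped$father[i], ped$mother[i], kids)
  }
  out <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == b && length(path) > 1) {
      # check the up-then-down shape
      dirs <- vapply(seq_len(length(path) - 1), function(k)
        if (parent_of(path[k], path[k + 1])) "up" else "down", "")
      if (!any(dirs == "up" & c(FALSE, head(dirs, -1) == "down"))) {
        out[[length(out) + 1L]] <<- list(ids = path,
                                         up = sum(dirs == "up"),
                                         down = sum(dirs == "down"))
      }
      return(invisible())
    }
    if (length(path) - 1 >= max_len) return(invisible())
    for (x in nbrs(cur)) {
      if (!is.na(x) && !(x %in% path)) walk(c(path, x))
    }
    invisible()
  }
  walk(a)
  out
}

# brute force affected-relative enumeration, applying the rules literally:
# depth-first over every simple up-then-down path, tracking the unaffected
# interior count and the first-step line, then the minimum/tie rules
oracle_links <- function(ped, proband, max_intermediates = 5,
                         include_descendants = TRUE, max_len = 14L) {
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  fa <- unname(ifelse(is.na(ped$father), 0L, idx[ped$father]))
  mo <- unname(ifelse(is.na(ped$mother), 0L, idx[ped$mother]))
  kids <- rep(list(integer()), n)
  for (i in seq_len(n)) {
    if (fa[i] > 0) kids[[fa[i]]] <- c(kids[[fa[i]]], i)
    if (mo[i] > 0) kids[[mo[i]]] <- c(kids[[mo[i]]], i)
  }
  unaff <- ped$affected != "affected"
  start <- idx[[proband]]
  best <- matrix(Inf, n, 3, dimnames = list(NULL, c("PA", "MA", "DE")))
  onpath <- logical(n)

  rec_down <- function(v, cost, line, len) {
    if (!unaff[v]) best[v, line] <<- min(best[v, line], cost)
    if (len >= max_len) return(invisible())
    extra <- if (v != start) as.integer(unaff[v]) else 0L
    for (k in kids[[v]]) {
      if (!onpath[k]) {
        onpath[k] <<- TRUE
        rec_down(k, cost + extra, line, len + 1L)
        onpath[k] <<- FALSE
      }
    }
    invisible()
  }
  rec_up <- function(v, cost, line, len) {
    if (v != start && !unaff[v]) best[v, line] <<- min(best[v, line], cost)
    if (len >= max_len) return(invisible())
    extra <- if (v != start) as.integer(unaff[v]) else 0L
    for (p in c(fa[v], mo[v])) {
      if (p > 0 && !onpath[p]) {
        l2 <- if (v == start) { if (p == fa[v]) "PA" else "MA" } else line
        onpath[p] <<- TRUE
        rec_up(p, cost + extra, l2, len + 1L)
        onpath[p] <<- FALSE
      }
    }
    # turn downward: v is the apex
    for (k in kids[[v]]) {
      if (!onpath[k]) {
        l2 <- if (v == start) "DE" else line
        onpath[k] <<- TRUE
        rec_down(k, cost + extra, l2, len + 1L)
        onpath[k] <<- FALSE
      }
    }
    invisible()
  }
  onpath[start] <- TRUE
  rec_up(start, 0L, "DE", 0L)

  rows <- list()
  for (b in setdiff(which(!unaff), start)) {
    pa <- best[b, "PA"]; ma <- best[b, "MA"]; de <- best[b, "DE"]
    bb <- min(pa, ma, de)
    if (bb > max_intermediates) next
    lab <- if (de <= min(pa, ma)) "descendant"
           else if (pa == bb && ma == bb) "ambiguous"
           else if (pa == bb) "PA" else "MA"
    if (!include_descendants && lab == "descendant") next
    rows[[length(rows) + 1L]] <- data.frame(
      proband = proband, relative = ped$id[b], line = lab,
      intermediates = as.integer(bb), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(proband = character(), relative = character(),
                      line = character(), intermediates = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$relative), , drop = FALSE]
}
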