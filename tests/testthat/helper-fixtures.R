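# Shared fixtures and independent oracles built in code.

# A fixed 7-term tree: R -> (A, B); A -> (A1, A2); B -> (B1); A2 -> (A2a)
toy_tree <- function() {
  ontology(
    terms = c("R", "A", "B", "A1", "A2", "B1", "A2a"),
    parents = list(R = character(0), A = "R", B = "R", A1 = "A", A2 = "A",
                   B1 = "B", A2a = "A2"))
}

# Diamond: child D under both parents P1 and P2, which sit under G
toy_diamond <- function() {
  ontology(
    terms = c("G", "P1", "P2", "D"),
    parents = list(G = character(0), P1 = "G", P2 = "G", D = c("P1", "P2")))
}

# Random rooted DAG: term i gets 1-2 parents among earlier terms
random_dag <- function(n, seed) {
  set.seed(seed)
  terms <- sprintf("T%03d", seq_len(n))
  parents <- list()
  parents[[terms[1]]] <- character(0)
  for (i in 2:n) {
    k <- sample(seq_len(min(2, i - 1)), 1)
    parents[[terms[i]]] <- sample(terms[seq_len(i - 1)], k)
  }
  ontology(terms, parents)
}

dag_edges <- function(g) {
  do.call(rbind, lapply(g$terms, function(t) {
    p <- g$parents[[t]]
    if (!length(p)) return(NULL)
    data.frame(child = t, parent = p, stringsAsFactors = FALSE)
  }))
}

# Brute-force descendant closure: expand edge list to a fixpoint
closure_bruteforce <- function(g, term) {
  edges <- dag_edges(g)
  out <- term
  repeat {
    add <- setdiff(edges$child[edges$parent %in% out], out)
    if (!length(add)) break
    out <- c(out, add)
  }
  sort(unique(out))
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value for
# a 2x2 table (a b / c d), margins fixed
fisher_p_bruteforce <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Conditional-MLE odds ratio for a 2x2 table via grid/uniroot on the
# noncentral hypergeometric mean equation
or_cmle_bruteforce <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  supp <- lo:hi
  mean_nchg <- function(lpsi) {
    lw <- dhyper(supp, m, n_, k, log = TRUE) + supp * lpsi
    w <- exp(lw - max(lw))
    sum(supp * w) / sum(w)
  }
  exp(uniroot(function(lp) mean_nchg(lp) - a, c(-30, 30), tol = 1e-10)$root)
}

# Hand-computed k-group log-rank statistic: at each distinct event time sum
# the hypergeometric observed-minus-expected increments and variance
logrank_bruteforce <- function(times, events, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  g1 <- levels(groups)[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & groups == g1)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & groups == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(o_minus_e = o_minus_e, var = v, chisq = o_minus_e^2 / v)
}

toy_lms <- function() {
  as_lms_reference(expand.grid(sex = c("F", "M"), gestational_weeks = 22:44,
                               stringsAsFactors = FALSE) |>
    transform(L = 1, M = 3000, S = 0.12))
}

# One fully passing rare-variant row; fields overridable
rv_row <- function(...) {
  base <- data.frame(proband_id = "P1", gene = "G1", consequence = "ptv",
                     loftee_confidence = "HC", mpc = NA_real_, pli = 0.95,
                     gnomad_max_maf = 0, cohort_maf = 0, inherited = TRUE,
                     autosomal = TRUE, zygosity = "het",
                     stringsAsFactors = FALSE)
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base
}
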