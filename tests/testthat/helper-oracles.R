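# Independent oracles and small fixture builders. Each oracle is a
# straight-line recomputation that shares no code with the package
# internals it checks.

# One-tailed Fisher p by explicit summation of the hypergeometric pmf
# over the support, using log-binomials only.
oracle_fisher <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0L, k - n2); hi <- min(n1, k)
  if (a > hi) return(0)
  ks <- max(a, lo):hi
  pmf <- exp(lchoose(n1, ks) + lchoose(n2, k - ks) - lchoose(n1 + n2, k))
  sum(pmf)
}

# Per-residue brute-force recomputation of a pair aggregate using explicit
# residue arrays and membership sets.
oracle_pair <- function(hits_ab, hits_ba, len_a, len_b) {
  dir_stats <- function(h, qlen) {
    arr <- rep(NA_real_, qlen)
    for (i in seq_len(nrow(h)))
      for (r in h$q_start[i]:h$q_end[i])
        arr[r] <- max(arr[r], h$probability[i], na.rm = TRUE)
    wid <- h$q_end - h$q_start + 1
    list(p = mean(arr[!is.na(arr)]),
         pid = sum(h$percent_identity * wid) / sum(wid))
  }
  member <- function(starts, ends, len) {
    s <- rep(FALSE, len)
    for (i in seq_along(starts)) s[starts[i]:ends[i]] <- TRUE
    s
  }
  dp <- c(); did <- c()
  if (nrow(hits_ab)) {
    st <- dir_stats(hits_ab, len_a); dp <- c(dp, st$p); did <- c(did, st$pid)
  }
  if (nrow(hits_ba)) {
    st <- dir_stats(hits_ba, len_b); dp <- c(dp, st$p); did <- c(did, st$pid)
  }
  a_mem <- member(c(hits_ab$q_start, hits_ba$s_start),
                  c(hits_ab$q_end, hits_ba$s_end), len_a)
  b_mem <- member(c(hits_ab$s_start, hits_ba$q_start),
                  c(hits_ab$s_end, hits_ba$q_end), len_b)
  list(p = min(dp), p_id = min(did),
       qcov = sum(a_mem) / len_a, scov = sum(b_mem) / len_b,
       aligned_len_a = sum(a_mem), aligned_len_b = sum(b_mem))
}

# Naive dense-matrix MCL, unpruned, interpreted directly from the limit
# matrix (attractor systems joined through column co-occurrence; each node
# assigned to the system with the largest mass in its column).
oracle_mcl <- function(nodes, edges, inflation = 2, expansion = 2,
                       max_iter = 200, tol = 1e-10) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- edges$id_a[r]; j <- edges$id_b[r]
    A[i, j] <- A[j, i] <- edges$weight[r]
  }
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  A <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M <- A
    for (e in seq_len(expansion - 1)) M <- M %*% A
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
    if (max(abs(M - A)) < tol) { A <- M; break }
    A <- M
  }
  eps <- 1e-9
  attract <- which(diag(A) > eps)
  label <- seq_len(n)
  repeat {
    changed <- FALSE
    for (col in seq_len(n)) {
      att <- intersect(which(A[, col] > eps), attract)
      if (length(att) > 1L) {
        m <- min(label[att])
        if (any(label[att] != m)) { label[att] <- m; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  assign <- integer(n)
  for (col in seq_len(n)) {
    att <- intersect(which(A[, col] > eps), attract)
    if (length(att) == 0L) { assign[col] <- label[col]; next }
    mass <- A[att, col]
    best <- att[mass >= max(mass) - eps]
    assign[col] <- min(label[best])
  }
  data.frame(rhmm_id = nodes, family_id = match(assign, sort(unique(assign))),
             stringsAsFactors = FALSE)
}

# Two partitions describe the same clustering (labels ignored)
same_partition <- function(p1, p2) {
  m <- match(p1$rhmm_id, p2$rhmm_id)
  if (anyNA(m)) return(FALSE)
  f1 <- p1$family_id
  f2 <- p2$family_id[m]
  all(tapply(f2, f1, function(x) length(unique(x)) == 1)) &&
    length(unique(f1)) == length(unique(f2))
}

random_weighted_graph <- function(n_nodes, p_edge = 0.15) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  prs <- t(combn(nodes, 2))
  keep <- runif(nrow(prs)) < p_edge
  edges <- data.frame(id_a = prs[keep, 1], id_b = prs[keep, 2],
                      weight = round(runif(sum(keep), 0.1, 1), 3),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "family_graph")
}

make_hits <- function(q, s, qi, si, p, pid, qlen, slen, tag = "self") {
  data.frame(query_id = q, subject_id = s, probability = p,
             percent_identity = pid,
             q_start = qi[, 1], q_end = qi[, 2],
             s_start = si[, 1], s_end = si[, 2],
             q_len = qlen, s_len = slen,
             search_tag = rep(tag, length.out = length(q)),
             stringsAsFactors = FALSE)
}

# random multi-HSP instance for one pair
random_pair_instance <- function() {
  len_a <- sample(80:300, 1); len_b <- sample(80:300, 1)
  rand_hits <- function(nh, qlen, slen, qid, sid) {
    if (nh == 0) return(make_hits(character(), character(),
                                  cbind(integer(), integer()),
                                  cbind(integer(), integer()),
                                  numeric(), numeric(), integer(), integer()))
    qs <- sample(seq_len(qlen - 10), nh, replace = TRUE)
    qe <- pmin(qlen, qs + sample(10:120, nh, replace = TRUE))
    ss <- sample(seq_len(slen - 10), nh, replace = TRUE)
    se <- pmin(slen, ss + sample(10:120, nh, replace = TRUE))
    make_hits(rep(qid, nh), rep(sid, nh), cbind(qs, qe), cbind(ss, se),
              runif(nh, 0.5, 1), runif(nh, 0.1, 0.9), qlen, slen)
  }
  n_ab <- sample(0:4, 1)
  n_ba <- sample(0:4, 1)
  if (n_ab + n_ba == 0) n_ab <- 1
  list(hits_ab = rand_hits(n_ab, len_a, len_b, "A", "B"),
       hits_ba = rand_hits(n_ba, len_b, len_a, "B", "A"),
       len_a = len_a, len_b = len_b)
}

# architecture stub from a T-group character vector
arch <- function(...) {
  t <- c(...)
  list(t_groups = sort(unique(t)),
       x_groups = sort(unique(as.integer(sub("\\..*", "", t)))),
       layout = NULL,
       architecture_key = paste(sort(unique(t)), collapse = "|"))
}

# one-row pair-comparison stub
pc_row <- function(id_a = "A", id_b = "B", p = 0.99, p_id = 0.5,
                   qcov = 0.3, scov = 0.3, la = 120L, lb = 120L,
                   ctx = "strict_p95") {
  data.frame(id_a = id_a, id_b = id_b, p = p, p_id = p_id, qcov = qcov,
             scov = scov, cov_min = min(qcov, scov),
             cov_max = max(qcov, scov), aligned_len_a = la,
             aligned_len_b = lb, threshold_context = ctx,
             stringsAsFactors = FALSE)
}
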