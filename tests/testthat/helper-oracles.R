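# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive every quantity by direct enumeration,
# never by calling the implementation under test.

# Random cohort with k binary condition columns, uniform times, Bernoulli
# events; condition prevalences drawn per column.
random_cohort <- function(n, k = 4, horizon = 5) {
  cond <- paste0("c", seq_len(k))
  out <- data.frame(id = seq_len(n),
                    age = sample(65:84, n, replace = TRUE),
                    male = rbinom(n, 1, 0.5))
  for (j in cond) out[[j]] <- rbinom(n, 1, runif(1, 0.05, 0.6))
  t_event <- rexp(n, 0.12)
  t_cens <- pmin(rexp(n, 0.06), horizon)
  out$time <- pmin(t_event, t_cens)
  out$event <- as.integer(t_event <= t_cens)
  out
}

# Cohort realising exact 2x2x2 counts for one condition pair vs death:
# n_both have the pair and die, n_ant - n_both have the pair and survive,
# n_death - n_both die without the pair.
counts_cohort <- function(n_total, n_death, n_ant, n_both,
                          pair = c("a", "b")) {
  stopifnot(n_both <= n_ant, n_both <= n_death,
            n_ant + n_death - n_both <= n_total)
  has_pair <- c(rep(1L, n_ant), rep(0L, n_total - n_ant))
  dies <- c(rep(1L, n_both), rep(0L, n_ant - n_both),
            rep(1L, n_death - n_both),
            rep(0L, n_total - n_ant - (n_death - n_both)))
  out <- data.frame(id = seq_len(n_total), age = 70L, male = 0L)
  out[[pair[1]]] <- has_pair
  out[[pair[2]]] <- has_pair
  out$time <- ifelse(dies == 1, 3.0, 5.0)
  out$event <- dies
  out
}

# Brute-force association-rule metrics by explicit row counting.
oracle_rule_metrics <- function(cohort, pair, horizon = 5) {
  n_total <- nrow(cohort)
  n_ant <- 0L; n_both <- 0L; n_death <- 0L
  for (i in seq_len(n_total)) {
    died <- cohort$event[i] == 1 && cohort$time[i] <= horizon
    has <- cohort[[pair[1]]][i] == 1 && cohort[[pair[2]]][i] == 1
    if (died) n_death <- n_death + 1L
    if (has) {
      n_ant <- n_ant + 1L
      if (died) n_both <- n_both + 1L
    }
  }
  list(support = n_both / n_total,
       confidence = if (n_ant > 0) n_both / n_ant else NA_real_,
       lift = if (n_ant > 0 && n_death > 0)
         (n_both / n_ant) / (n_death / n_total) else NA_real_,
       prevalence = n_ant / n_total,
       counts = c(n_ant = n_ant, n_both = n_both, n_death = n_death,
                  n_total = n_total))
}

# All-pairs concordance oracle: explicit double enumeration of the
# comparability and credit rules.
oracle_harrell_c <- function(time, event, risk) {
  n <- length(time)
  num <- 0; comparable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] == 1 && event[j] == 1) {
          comparable <- comparable + 1
          num <- num + 0.5
        }
        next
      }
      early <- if (time[i] < time[j]) i else j
      late <- if (time[i] < time[j]) j else i
      if (event[early] != 1) next
      comparable <- comparable + 1
      if (risk[early] > risk[late]) num <- num + 1
      else if (risk[early] == risk[late]) num <- num + 0.5
    }
  }
  if (comparable == 0) stop("no comparable pairs")
  num / comparable
}

# Negative Efron-corrected Cox log partial likelihood, written from the
# definition; optimised with optim() as an independent fitting route.
oracle_cox_efron <- function(x, time, event, init = NULL) {
  x <- as.matrix(x)
  negll <- function(beta) {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    ll <- 0
    for (t in unique(time[event == 1])) {
      D <- which(event == 1 & time == t)
      R <- which(time >= t)
      d <- length(D)
      sumD <- sum(w[D]); sumR <- sum(w[R])
      ll <- ll + sum(eta[D])
      for (l in seq_len(d) - 1) {
        ll <- ll - log(sumR - (l / d) * sumD)
      }
    }
    -ll
  }
  if (is.null(init)) init <- rep(0, ncol(x))
  fit <- optim(init, negll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  fit$par
}

# Hand-tallied continuous NRI from the definition.
oracle_nri <- function(risk_old, risk_new, outcome) {
  ev <- which(outcome == 1); ne <- which(outcome == 0)
  up <- risk_new > risk_old; down <- risk_new < risk_old
  (sum(up[ev]) - sum(down[ev])) / length(ev) +
    (sum(down[ne]) - sum(up[ne])) / length(ne)
}

# Small all-conditions / no-conditions profiles on the canonical schema.
schema_cohort <- function(profiles, time = 5, event = 0) {
  cond <- clhls_conditions()
  out <- data.frame(id = seq_len(nrow(profiles)), age = 70L, male = 0L)
  for (j in cond) out[[j]] <- profiles[, j]
  out$time <- time
  out$event <- event
  out
}
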