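# Link functions for parametric discrete hazard models.
#
# logit gives the continuation-ratio model (proportional conditional odds);
# cloglog is the grouped proportional-hazards model, the discrete-time
# analogue of the Cox model; probit, loglog (Gumbel) and log (exponential)
# are the usual alternatives. stats::binomial() supplies all but loglog,
# which is built by hand.

dt_links <- c("logit", "cloglog", "probit", "loglog", "log")

loglog_link <- function() {
  eps <- 1e-12
  structure(list(
    linkfun = function(mu) -log(-log(pmin(pmax(mu, eps), 1 - eps))),
    linkinv = function(eta) pmin(pmax(exp(-exp(-eta)), eps), 1 - eps),
    mu.eta  = function(eta) pmax(exp(-eta - exp(-eta)), eps),
    valideta = function(eta) TRUE,
    name = "loglog"), class = "link-glm")
}

dt_family <- function(link) {
  link <- match.arg(link, dt_links)
  if (link == "loglog") stats::binomial(link = loglog_link())
  else stats::binomial(link = link)
}

dt_linkinv <- function(link) dt_family(link)$linkinv
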