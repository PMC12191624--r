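Package: mutationsampler
Title: Mutation-Sampler Models of Human Causal Reasoning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact engines for small binary causal Bayesian networks
    (logistic conditional probability tables, joint enumeration,
    conditional-probability queries) together with the mutation sampler, a
    resource-limited Metropolis-Hastings process model of human causal
    inference that starts its chains at qualitatively consistent prototype
    states. Includes the Markov-violation summary statistic for
    screening-off designs, per-subject least-squares model fitting with AIC
    comparison, group-level inferential statistics (one-way ANOVA,
    one-sample t, JZS Bayes factor), and a seeded synthetic-subject
    generator so the full analysis pipeline runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
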