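column,type,description
approach,string,"estimator: unregularized, normal (informative prior) or cauchy (weakly-informative prior)"
T_occasions,integer,number of evenly spaced sampling occasions in the scenario
r,numeric,true remaining fraction of the population at the end of the study period (1 = null)
cv_lower,numeric,lower bound of the uniform CV distribution of abundance estimates
cv_upper,numeric,upper bound of the uniform CV distribution of abundance estimates
alpha,numeric,significance level; confidence intervals are at level 1 - alpha
n_reps,integer,number of Monte Carlo replicates in the cell
rejection_rate,numeric,fraction of replicates with p < alpha (power if r < 1; type-I error if r = 1)
n_significant,integer,count of significant replicates (rejection_rate * n_reps exactly)
type_s_rate,numeric,"among significant replicates, fraction with the wrong trend sign; NA if r = 1 or none significant"
type_m_ratio,numeric,"exaggeration ratio mean(|beta_hat|)/|log r| over significant replicates; NA if r = 1 or none significant"
bias_r,numeric,mean(exp(beta_hat)) - r over all replicates (remaining-fraction scale)
bias_beta,numeric,mean(beta_hat) - log(r) over all replicates (log scale)
coverage,numeric,fraction of confidence intervals containing the true r
coverage_significant,numeric,same restricted to significant replicates; NA if none significant
n_degenerate,integer,count of perfect-fit (zero-residual) replicates
scenario_id,integer,1-based index of the scenario in the grid (drives the substream seed)
error,string,error message if the cell failed; NA otherwise
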