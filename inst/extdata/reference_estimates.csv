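objective,model,alpha_s,beta_s,alpha_o,beta_o,lambda,statistic,value
sse,markov,339.53,330.37,419.82,402.93,0.90,r2,0.54
sse,quantum,99.24,-14.57,89.53,-16.74,0.94,r2,0.90
likelihood,markov,317.63,313.72,283.87,270.94,0.91,g2,1190
likelihood,quantum,114.58,-13.28,92.43,-17.56,0.91,g2,839
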