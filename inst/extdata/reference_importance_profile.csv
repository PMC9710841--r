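feature,extra,agree,consc,stabl,open,average
efficiency,100.00,71.51,100.00,85.03,100.00,91.31
reach_efficiency,56.04,60.21,95.65,100.00,63.19,75.02
constraint,80.30,70.00,79.67,67.61,22.17,63.95
closeness_centrality,71.78,93.77,64.25,54.41,33.48,63.54
effective_size,47.72,100.00,29.50,62.61,43.91,56.75
betweenness_ego,54.69,60.23,46.94,44.11,22.25,45.65
betweenness_centrality,57.14,25.50,47.60,61.80,33.87,45.18
community_percent_size,37.78,23.65,59.92,50.67,46.35,43.67
transitivity_ego,36.44,32.43,48.48,48.55,33.35,39.85
density_ego,32.81,48.71,48.47,18.71,48.35,39.41
avg_similarity,26.16,64.69,32.35,42.60,13.08,35.78
size_ego,58.47,30.26,23.74,15.98,1.50,25.99
centralization_ego,24.76,40.75,26.60,21.33,11.66,25.02
avg_dyadic_redundancy,15.93,37.16,21.84,20.76,17.37,22.61
degree_centrality,32.83,33.08,22.27,12.19,12.64,22.60
week,11.94,20.34,10.93,17.09,0.24,12.11
size,18.25,9.84,8.86,6.23,7.32,10.10
centralization,7.41,9.39,9.32,6.83,8.52,8.29
geodesic_distance_ego,13.51,3.37,4.31,0.47,9.81,6.29
transitivity,9.95,0.00,6.90,0.45,0.00,3.46
density,5.92,3.61,4.07,2.01,0.00,3.12
geodesic_distance,0.44,3.36,0.74,2.50,3.94,2.20
n_ordered_pairs_ego,6.62,3.66,0.00,0.00,0.00,2.06
diameter,4.43,0.00,2.99,2.30,0.00,1.94
order,7.05,0.00,1.27,0.38,0.00,1.74
n_ordered_pairs,1.21,0.00,2.54,0.51,0.00,0.85
n_subcommunities,0.00,0.00,0.00,0.14,0.00,0.03
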