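metric,modality,label,median,ci_low,ci_high,units
pct_localizations_in_nanoclusters,STORM,BTX,29.12,24.31,36.34,percent
pct_localizations_in_nanoclusters,STORM,mAb,56.04,53.18,60.17,percent
nanocluster_area,STORM,BTX,0.0025,0.0024,0.0026,um2
nanocluster_area,STORM,mAb,0.0013,0.0013,0.0014,um2
nanocluster_area,STED,BTX,0.004,0.003,0.005,um2
nanocluster_area,STED,mAb,0.001,0.0006,0.0017,um2
molecule_density,STORM,BTX,8726,8422,9025,per_um2
molecule_density,STORM,mAb,19661,18941,20408,per_um2
localizations_per_nanocluster,STORM,BTX,20,20,21,count
localizations_per_nanocluster,STORM,mAb,25,24,26,count
inter_centroid_distance,STORM,BTX,2.25,2.24,2.26,um
inter_centroid_distance,STORM,mAb,1.58,1.57,1.59,um
inter_centroid_distance,STED,BTX,4.42,4.36,4.47,um
inter_centroid_distance,STED,mAb,3.2,3.06,3.32,um
eccentricity,STORM,BTX,0.72,0.71,0.73,ratio
eccentricity,STORM,mAb,0.69,0.68,0.70,ratio
eccentricity,STED,BTX,0.93,0.91,0.94,ratio
eccentricity,STED,mAb,0.89,0.85,0.94,ratio
major_axis_length,STORM,BTX,0.086,0.084,0.088,um
major_axis_length,STORM,mAb,0.061,0.060,0.063,um
major_axis_length,STED,BTX,0.360,0.332,0.399,um
major_axis_length,STED,mAb,0.150,0.107,0.267,um
inter_particle_distance,STORM,BTX,42.42,42.23,42.63,nm
inter_particle_distance,STORM,mAb,14.23,14.17,14.28,nm
inter_particle_distance,STED,BTX,366.5,362.6,369.7,nm
inter_particle_distance,STED,mAb,153.9,150.5,158.4,nm
nearest_particle_distance,STORM,BTX,15.70,15.50,15.80,nm
nearest_particle_distance,STORM,mAb,11.20,11.10,11.20,nm
nearest_particle_distance,STED,BTX,75.70,70.40,80.70,nm
nearest_particle_distance,STED,mAb,20.65,19.50,22.70,nm
max_clustering_distance,STORM,BTX,47.00,41.60,51.00,nm
max_clustering_distance,STORM,mAb,109.0,72.20,208.0,nm
max_clustering_distance,STED,BTX,317.5,300.0,357.0,nm
max_clustering_distance,STED,mAb,354.0,311.0,566.0,nm
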